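# Inventory of magnetochrome-containing proteins across ten magnetotactic
# bacteria: one row per protein, with the number of MCR domains it carries.
# Architecture notes record deviations from the canonical tandem.
strain	protein	family	n_mcr	architecture
AMB-1	MamE	MamE	2	Trypsin-MCR1-MCR2-PDZ-PDZ
AMB-1	MamE-like	MamE	4	four MCR domains (genomic islet paralog)
AMB-1	LimE	MamE	4	four MCR domains (island paralog)
AMB-1	MamP	MamP	2	PDZ-MCR1-MCR2
AMB-1	MamT	MamT	2	MCR1-MCR2
AMB-1	MamX	MamX	2	MCR1-MCR2
MSR-1	MamE	MamE	2	Trypsin-MCR1-MCR2-PDZ-PDZ
MSR-1	MamP	MamP	2	PDZ-MCR1-MCR2
MSR-1	MamT	MamT	2	MCR1-MCR2
MSR-1	MamX	MamX	2	MCR1-MCR2
MS-1	MamE	MamE	2	Trypsin-MCR1-MCR2-PDZ-PDZ
MS-1	MamE'	MamE	2	second MamE paralog
MS-1	MamP	MamP	2	PDZ-MCR1-MCR2
MS-1	MamT	MamT	2	MCR1-MCR2
MS-1	MamX	MamX	2	MCR1-MCR2
MC-1	MamE	MamE	3	MCR triplicate
MC-1	MamP	MamP	2	PDZ-MCR1-MCR2
MC-1	MamT	MamT	2	MCR1-MCR2
MC-1	MamX	MamX	2	MCR1-MCR2
MV-1	MamE	MamE	2	Trypsin-MCR1-MCR2-PDZ-PDZ
MV-1	MamP	MamP	2	PDZ-MCR1-MCR2
MV-1	MamT	MamT	2	MCR1-MCR2
MV-1	MamX	MamX	2	MCR1-MCR2
QH-2	MamE	MamE	2	Trypsin-MCR1-MCR2-PDZ-PDZ
QH-2	MamP	MamP	2	PDZ-MCR1-MCR2
QH-2	MamT	MamT	2	MCR1-MCR2
QH-2	MamX	MamX	2	MCR1-MCR2
SS-5	MamE	MamE	4	MCRA1-MCRA2-Trypsin-MCR1-MCR2-PDZ
SS-5	MamE'	MamE	1	Trypsin-MCR0-PDZ
SS-5	MamP	MamP	2	PDZ-MCR1-MCR2
SS-5	MamT	MamT	2	MCR1-MCR2
RS-1	MamE	MamE	2	Trypsin-MCR1-MCR2-TauE
RS-1	MamP*	other	2	MCR1-MCR2-PDZ-NitroFeMoCo
BW-1	MamE	MamE	2	Trypsin-MCR1-MCR2-TauE
BW-1	MamP*	other	2	MCR1-MCR2-PDZ-NitroFeMoCo
M.bavaricum	MamE	MamE	1	Trypsin-MCR0-PDZ
M.bavaricum	MamP	MamP	2	PDZ-MCR1-MCR2
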