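name	consensus	category	note
TATA-box	TATAAA	essential	core promoter element around -30
CAAT-box	CCAAT	essential	common cis-element in promoter and enhancer regions
5UTR-Py-rich-stretch	TTTCTTCTCT	enhancer	element conferring high transcription levels
Gap-box	CAAATGAARA	light	part of a light responsive element
AE-box	AGAAACAA	light	part of a module for light response
ATCT-motif	AATCTAATCC	light	part of a conserved DNA module involved in light responsiveness
Box-4	ATTAAT	light	part of a conserved DNA module involved in light responsiveness
G-box	CACGTG	light	light responsive element
AACA_motif	AACAAAC	tissue	endosperm-specific negative expression
CCGTCC-box	CCGTCC	tissue	meristem-specific activation
MBS	CAACTG	abiotic	MYB binding site involved in drought inducibility
LTR	CCGAAA	abiotic	low-temperature responsive element
DRE	RCCGAC	abiotic	dehydration/low temperature/salt responsive element
HSE	AAAAAATTTC	abiotic	heat stress responsive element
TC-rich-repeats	ATTTTCTCCA	abiotic	defense and stress responsive element (canonical core)
WUN-motif	AAATTTCCT	abiotic	wound-responsive element
ABRE	ACGTG	hormone	abscisic acid responsive element
CGTCA-motif	CGTCA	hormone	MeJA responsive element
TGACG-motif	TGACG	hormone	MeJA responsive element
P-box	CCTTTTG	hormone	gibberellin responsive element
TATC-box	TATCCCA	hormone	gibberellin responsive element
GARE-motif	TCTGTTG	hormone	gibberellin responsive element
TCA-element	CCATCTTTTT	hormone	salicylic acid responsive element
SARE	TTCGACCATCTT	hormone	salicylic acid responsive element
TGA-element	AACGAC	hormone	auxin responsive element
AuxRR-core	GGTCCAT	hormone	auxin responsive element
ELI-box3	AAACCAATT	hormone	elicitor/hormone responsive element
W-box	TTGACC	other	WRKY binding site
circadian	CAANNNNATC	other	circadian control element
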