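abbreviation	name
ATR_L	Left Anterior Thalamic
ATR_R	Right Anterior Thalamic
CST_L	Left Corticospinal
CST_R	Right Corticospinal
CGC_L	Left Cingulum Cingulate
CGC_R	Right Cingulum Cingulate
IFO_L	Left Inferior Fronto-Occipital
IFO_R	Right Inferior Fronto-Occipital
ILO_L	Left Inferior Longitudinal
ILO_R	Right Inferior Longitudinal
SLF_L	Left Superior Longitudinal
SLF_R	Right Superior Longitudinal
UNC_L	Left Uncinate
UNC_R	Right Uncinate
ARC_L	Left Arcuate
ARC_R	Right Arcuate
pARC_L	Left Posterior Arcuate
pARC_R	Right Posterior Arcuate
VOF_L	Left Vertical Occipital
VOF_R	Right Vertical Occipital
Orbital	Orbital Corpus Callosum
AntFrontal	Anterior Frontal Callosum
SupFrontal	Superior Frontal Callosum
Motor	Motor Corpus Callosum
SupParietal	Superior Parietal Corpus Callosum
PostParietal	Posterior Parietal Corpus Callosum
Temporal	Temporal Corpus Callosum
Occipital	Occipital Corpus Callosum
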