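species,sample,compound,delta_ad_permil,delta_ab_permil
Eucalyptus_diversicolor_shade,1,C25_alkane,-33.57,-33.92
Eucalyptus_diversicolor_shade,2,C27_alkane,-32.28,-34.17
Eucalyptus_diversicolor_shade,3,C29_alkane,-30.20,-31.61
Eucalyptus_diversicolor_shade,4,C31_alkane,-29.60,-31.53
Eucalyptus_diversicolor_shade,5,C33_alkane,-32.65,-33.20
Eucalyptus_diversicolor_shade,6,C26_ol,-34.50,-35.23
Eucalyptus_diversicolor_shade,7,C28_ol,-31.72,-32.94
Eucalyptus_diversicolor_sun,1,C25_alkane,-33.85,-34.13
Eucalyptus_diversicolor_sun,2,C27_alkane,-34.98,-35.45
Eucalyptus_diversicolor_sun,3,C29_alkane,-29.64,-31.21
Eucalyptus_diversicolor_sun,4,C31_alkane,-36.41,-35.58
Eucalyptus_diversicolor_sun,5,C33_alkane,-29.48,-30.04
Eucalyptus_diversicolor_sun,6,C26_ol,-29.02,-30.25
Eucalyptus_diversicolor_sun,7,C28_ol,-32.31,-34.06
HS_species_1,1,C27_alkane,-29.08,-30.37
HS_species_1,2,C29_alkane,-35.27,-35.76
HS_species_1,3,C31_alkane,-28.87,-30.74
HS_species_1,4,C33_alkane,-32.59,-33.85
HS_species_1,5,C26_ol,-33.88,-34.11
HS_species_2,1,C27_alkane,-30.66,-32.27
HS_species_2,2,C29_alkane,-33.34,-34.76
HS_species_2,3,C31_alkane,-34.35,-34.72
HS_species_2,4,C28_ol,-31.87,-32.74
HS_species_2,5,C30_ol,-30.46,-32.39
HS_species_3,1,C29_alkane,-34.25,-34.88
HS_species_3,2,C31_alkane,-31.59,-30.86
HS_species_3,3,C33_alkane,-31.95,-32.66
HS_species_3,4,C28_ol,-34.16,-35.94
HS_species_4,1,C25_alkane,-33.24,-32.47
HS_species_4,2,C27_alkane,-32.91,-34.67
HS_species_4,3,C29_alkane,-32.02,-33.61
HS_species_4,4,C31_alkane,-30.60,-30.84
HS_species_4,5,C26_ol,-29.83,-30.26
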