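plot_code,richness,shannon,stems,evenness,map_mm,agb_t,annual_agb_change_t,lambda_pct,mu_pct,turnover_pct
FLP-01,181,4.64,583,0.892,1982,317,10.3,1.36,3.31,2.23
TAM-01,174,4.08,620,0.791,2484,269,2.5,1.91,1.83,1.87
TAM-02,197,4.29,682,0.812,2475,288,-3.4,2.42,2.47,2.45
TAM-04,147,4.71,303,0.943,2471,333,1.3,2.12,1.40,1.76
TAM-05,161,4.52,535,0.889,2451,287,3.5,1.99,1.84,1.91
TAM-06,193,4.25,663,0.807,2497,340,5.4,1.56,2.13,1.85
TAM-07,154,4.34,509,0.862,2441,267,-6.6,3.10,2.66,2.88
TAM-08,143,4.36,517,0.878,2451,246,0.8,2.57,2.21,2.39
TAM-09,187,4.54,556,0.869,2457,271,-9.6,2.00,1.28,1.64
TRC-01,139,4.05,535,0.821,3292,267,-4.6,2.37,2.16,2.25
ALM-01,320,5.00,1324,0.866,2469,296,,,,
CUZ-01,134,4.25,435,0.867,2060,269,,,,
CUZ-02,133,3.92,556,0.801,2060,291,,,,
CUZ-03,138,4.14,505,0.840,2049,280,,,,
CUZ-04,157,4.37,602,0.863,2050,306,,,,
LAS-02,186,4.32,592,0.827,2600,284,,,,
MNU-05,194,4.28,1234,0.812,2546,342,,,,
MNU-06,202,4.32,1212,0.813,2567,322,,,,
POR-01,152,4.45,551,0.886,1688,367,,,,
POR-02,160,4.39,520,0.864,1686,249,,,,
RFH-01,145,4.44,383,0.892,1719,304,,,,
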