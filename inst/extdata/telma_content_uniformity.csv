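tablet,TEL_SRS,TEL_SDS,TEL_iPLS,TEL_GAPLS,CHT_SRS,CHT_SDS,CHT_iPLS,CHT_GAPLS,AML_SRS,AML_SDS,AML_iPLS,AML_GAPLS
1,101.32,98.55,100.54,100.47,100.84,101.94,99.46,99.46,100.15,99.14,99.49,99.04
2,100.27,98.79,101.65,99.55,102.10,99.43,100.04,100.04,99.04,101.31,101.05,100.25
3,98.75,100.12,101.59,100.40,98.89,99.66,101.00,101.00,101.92,100.90,103.11,101.71
4,99.81,100.53,99.92,99.88,99.20,103.09,99.74,101.13,100.19,102.13,100.85,101.50
5,99.80,98.56,98.87,99.10,103.42,98.51,100.39,102.03,97.87,100.49,97.91,101.73
6,101.42,99.24,99.96,99.97,99.05,99.66,98.53,100.66,98.21,102.87,98.37,98.76
7,100.82,99.58,99.49,97.76,98.33,100.80,100.36,97.96,101.92,98.85,98.58,99.51
8,100.17,100.76,98.43,100.00,101.96,99.54,100.29,99.08,99.42,101.39,97.82,99.78
9,99.94,100.61,99.96,98.65,100.51,101.94,102.50,100.37,100.58,98.61,97.90,97.55
10,100.96,98.79,100.94,99.11,100.84,99.66,101.29,100.77,100.15,100.90,97.80,97.83
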