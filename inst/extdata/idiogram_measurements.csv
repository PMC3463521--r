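cell_id,chrom_index,homolog_id,relative_length,arm_ratio,has_5S_signal
idiogram_I,1,1,16.61,1.23,TRUE
idiogram_I,1,2,16.61,1.23,TRUE
idiogram_I,2,1,13.92,2.51,FALSE
idiogram_I,2,2,13.92,2.51,FALSE
idiogram_I,3,1,11.50,2.31,FALSE
idiogram_I,3,2,11.50,2.31,FALSE
idiogram_I,4,1,10.77,1.52,FALSE
idiogram_I,4,2,10.77,1.52,FALSE
idiogram_I,5,1,9.85,1.35,FALSE
idiogram_I,5,2,9.85,1.35,FALSE
idiogram_I,6,1,6.09,1.27,FALSE
idiogram_I,6,2,6.09,1.27,FALSE
idiogram_I,7,1,5.38,2.37,FALSE
idiogram_I,7,2,5.38,2.37,FALSE
idiogram_I,8,1,5.25,1.38,FALSE
idiogram_I,8,2,5.25,1.38,FALSE
idiogram_I,9,1,4.89,2.11,FALSE
idiogram_I,9,2,4.89,2.11,FALSE
idiogram_I,10,1,4.64,1.28,FALSE
idiogram_I,10,2,4.64,1.28,FALSE
idiogram_I,11,1,4.12,1.18,FALSE
idiogram_I,11,2,4.12,1.18,FALSE
idiogram_I,12,1,3.68,1.19,FALSE
idiogram_I,12,2,3.68,1.19,FALSE
idiogram_I,13,1,3.30,1.19,FALSE
idiogram_I,13,2,3.30,1.19,FALSE
idiogram_IV,1,1,13.03,1.19,TRUE
idiogram_IV,1,2,8.32,7.11,TRUE
idiogram_IV,2,1,11.34,2.49,FALSE
idiogram_IV,2,2,11.34,2.49,FALSE
idiogram_IV,3,1,9.63,2.54,FALSE
idiogram_IV,3,2,9.63,2.54,FALSE
idiogram_IV,4,1,8.96,1.47,FALSE
idiogram_IV,4,2,8.96,1.47,FALSE
idiogram_IV,5,1,8.19,1.32,FALSE
idiogram_IV,5,2,8.19,1.32,FALSE
idiogram_IV,6,1,5.01,1.17,FALSE
idiogram_IV,6,2,9.02,3.35,FALSE
idiogram_IV,7,1,4.69,2.04,FALSE
idiogram_IV,7,2,4.69,2.04,FALSE
idiogram_IV,8,1,4.38,1.25,FALSE
idiogram_IV,8,2,4.38,1.25,FALSE
idiogram_IV,9,1,4.08,2.00,FALSE
idiogram_IV,9,2,4.08,2.00,FALSE
idiogram_IV,10,1,3.92,1.22,FALSE
idiogram_IV,10,2,3.92,1.22,FALSE
idiogram_IV,11,1,3.47,1.23,FALSE
idiogram_IV,11,2,3.47,1.23,FALSE
idiogram_IV,12,1,3.19,1.16,FALSE
idiogram_IV,12,2,3.19,1.16,FALSE
idiogram_IV,13,1,2.76,1.18,FALSE
idiogram_IV,13,2,2.76,1.18,FALSE
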