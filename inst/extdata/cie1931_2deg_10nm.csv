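"wavelength_nm","xbar","ybar","zbar"
400,0.01431,0.000396,0.06785
410,0.04351,0.00121,0.2074
420,0.13438,0.004,0.6456
430,0.2839,0.0116,1.3856
440,0.34828,0.023,1.74706
450,0.3362,0.038,1.77211
460,0.2908,0.06,1.6692
470,0.19536,0.09098,1.28764
480,0.09564,0.13902,0.81295
490,0.03201,0.20802,0.46518
500,0.0049,0.323,0.272
510,0.0093,0.503,0.1582
520,0.06327,0.71,0.07825
530,0.1655,0.862,0.04216
540,0.2904,0.954,0.0203
550,0.43345,0.99495,0.00875
560,0.5945,0.995,0.0039
570,0.7621,0.952,0.0021
580,0.9163,0.87,0.00165
590,1.0263,0.757,0.0011
600,1.0622,0.631,8e-04
610,1.0026,0.503,0.00034
620,0.85445,0.381,0.00019
630,0.6424,0.265,5e-05
640,0.4479,0.175,2e-05
650,0.2835,0.107,0
660,0.1649,0.061,0
670,0.0874,0.032,0
680,0.04677,0.017,0
690,0.0227,0.00821,0
700,0.011359,0.004102,0
710,0.00579,0.002091,0
720,0.002899,0.001047,0
730,0.00144,0.00052,0
740,0.00069,0.000249,0
750,0.000332,0.00012,0
760,0.000166,6e-05,0
770,8.3e-05,3e-05,0
780,4.2e-05,1.5e-05,0
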