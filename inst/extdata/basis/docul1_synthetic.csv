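# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,value
390,1.45000000000000e+00
395,1.29751700938084e+00
400,1.16106923422937e+00
405,1.03897040033199e+00
410,9.29711563223434e-01
415,8.31942460069277e-01
420,7.44454822597258e-01
425,6.66167444852094e-01
430,5.96112821235422e-01
435,5.33425189698591e-01
440,4.77329832321463e-01
445,4.27133501049656e-01
450,3.82215850267804e-01
455,3.42021770329265e-01
460,3.06054527297081e-01
465,2.73869624114465e-01
470,2.45069307338796e-01
475,2.19297651551219e-01
480,1.96236160693088e-01
485,1.75599831968878e-01
490,1.57133633671749e-01
495,1.40609353403387e-01
500,1.25822777737197e-01
505,1.12591168470040e-01
510,1.00751004273062e-01
515,9.01559598320687e-02
520,8.06750975028721e-02
525,7.21912491334027e-02
530,6.45995680545100e-02
535,5.78062333444012e-02
540,5.17272903535160e-02
545,4.62876131605988e-02
550,4.14199761375980e-02
555,3.70642231494357e-02
560,3.31665241212964e-02
565,2.96787097858082e-02
570,2.65576763886646e-02
575,2.37648529958097e-02
580,2.12657248189643e-02
585,1.90294066685644e-02
590,1.70282612626810e-02
595,1.52375576748340e-02
600,1.36351656996680e-02
605,1.22012823593417e-02
610,1.09181871706925e-02
615,9.77002314867393e-03
620,8.74260083961996e-03
625,7.82322296250625e-03
630,7.00052749105559e-03
635,6.26434723743640e-03
640,5.60558420223557e-03
645,5.01609713787390e-03
650,4.48860093592960e-03
655,4.01657659495958e-03
660,3.59419065616622e-03
665,3.21622311126437e-03
670,2.87800289160640e-03
675,2.57535014131485e-03
680,2.30452456101197e-03
685,2.06217918375789e-03
690,1.84531901194272e-03
695,1.65126400395139e-03
700,1.47761595317602e-03
705,1.32222885005405e-03
710,1.18318236085461e-03
715,1.05875809545396e-03
720,9.47418370807702e-04
725,8.47787207670947e-04
730,7.58633325716233e-04
735,6.78854926896526e-04
740,6.07466079000157e-04
745,5.43584531120404e-04
750,4.86420810458642e-04
755,4.35268465715104e-04
760,3.89495336491342e-04
765,3.48535740808295e-04
770,3.11883484190285e-04
775,2.79085603918520e-04
780,2.49736771143175e-04
785,2.23474281673185e-04
790,1.99973573538015e-04
795,1.78944215925685e-04
800,1.60126319926823e-04
805,1.43287326727318e-04
810,1.28219133556830e-04
815,1.14735521874525e-04
820,1.02669856008540e-04
825,9.18730238081115e-05
830,8.22115938581207e-05
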