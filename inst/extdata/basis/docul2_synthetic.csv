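# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,value
390,4.50000000000000e-01
395,3.97123606163068e-01
400,3.50460352382132e-01
405,3.09280175455938e-01
410,2.72938796870685e-01
415,2.40867642833546e-01
420,2.12564948733457e-01
425,1.87587908855329e-01
430,1.65545748527149e-01
435,1.46093610311257e-01
440,1.28927158587086e-01
445,1.13777818112136e-01
450,1.00408572066793e-01
455,8.86102538418873e-02
460,7.81982745527003e-02
465,6.90097350802178e-02
470,6.09008774564757e-02
475,5.37448357200238e-02
480,4.74296510528390e-02
485,4.18565201447986e-02
490,3.69382493807545e-02
495,3.25978906654132e-02
500,2.87675375430184e-02
505,2.53872627766998e-02
510,2.24041807655388e-02
515,1.97716201305333e-02
520,1.74483935242749e-02
525,1.53981532402497e-02
530,1.35888225400433e-02
535,1.19920938013600e-02
540,1.05829856352041e-02
545,9.33945204316488e-03
550,8.24203749993038e-03
555,7.27357256467464e-03
560,6.41890525904967e-03
565,5.66466400909530e-03
570,4.99904844220904e-03
575,4.41164476611982e-03
580,3.89326284140429e-03
585,3.43579239848698e-03
590,3.03207614958846e-03
595,2.67579781041244e-03
600,2.36138327963162e-03
605,2.08391343008996e-03
610,1.83904714730883e-03
615,1.62295341120708e-03
620,1.43225135842935e-03
625,1.26395738753648e-03
630,1.11543847949986e-03
635,9.84371003182298e-04
640,8.68704361302469e-04
645,7.66628908111158e-04
650,6.76547636839908e-04
655,5.97051193962146e-04
660,5.26895829356029e-04
665,4.64983937391437e-04
670,4.10346884499532e-04
675,3.62129854556076e-04
680,3.19578474979147e-04
685,2.82027014301806e-04
690,2.48887966566525e-04
695,2.19642859585537e-04
700,1.93834143259059e-04
705,1.71058031041259e-04
710,1.50958182556130e-04
715,1.33220128525585e-04
720,1.17566350785750e-04
725,1.03751940416599e-04
730,9.15607660547899e-05
735,8.08020924416248e-05
740,7.13075963020881e-05
745,6.29287328673455e-05
750,5.55344118390058e-05
755,4.90089464347799e-05
760,4.32502434276276e-05
765,3.81682058609111e-05
770,3.36833234494653e-05
775,2.97254286129082e-05
780,2.62325986788910e-05
785,2.31501870808660e-05
790,2.04299683931182e-05
795,1.80293838268280e-05
800,1.59108753826845e-05
805,1.40412982426286e-05
810,1.23914022073862e-05
815,1.09353740666983e-05
820,9.65043374246512e-06
825,8.51647788632334e-06
830,7.51576535561055e-06
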