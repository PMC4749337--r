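# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,value
390,7.41107431163491e-01
395,8.05543068173779e-01
400,8.65464673135260e-01
405,9.17853978453963e-01
410,9.59693634565552e-01
415,9.88012746274804e-01
420,1.00000000000000e+00
425,9.93239199173209e-01
430,9.66084323327619e-01
435,9.18116919528194e-01
440,8.50541477533945e-01
445,7.66332945623339e-01
450,6.70014970974477e-01
455,5.67110100134167e-01
460,4.63455536112451e-01
465,3.64589000160685e-01
470,2.75265440490931e-01
475,1.99022274753205e-01
480,1.37757888848349e-01
485,9.14997200994350e-02
490,5.86150847481567e-02
495,3.64676956030189e-02
500,2.22042456891869e-02
505,1.33270989413689e-02
510,7.93391752654207e-03
515,4.70774503890574e-03
520,2.79447557582707e-03
525,1.66376859454625e-03
530,9.95374788031594e-04
535,5.99127264103462e-04
540,3.63112555375808e-04
545,2.21703127986295e-04
550,1.36406994592635e-04
555,8.45857484530827e-05
560,5.28652793532337e-05
565,3.32999265270443e-05
570,2.11388539591442e-05
575,1.35218852226508e-05
580,8.71472931110763e-06
585,5.65807792141418e-06
590,3.70012553285668e-06
595,2.43685059414963e-06
600,1.61598763681993e-06
605,1.07888656979015e-06
610,7.25061415574873e-07
615,4.90420652416501e-07
620,3.33804858607015e-07
625,2.28603545664332e-07
630,1.57498959887762e-07
635,1.09148169917793e-07
640,7.60747465664516e-08
645,5.33203180039505e-08
650,3.75766093958125e-08
655,2.66232553010763e-08
660,1.89614280469813e-08
665,1.35736413101532e-08
670,9.76534800542657e-09
675,7.05987684173943e-09
680,5.12835362209284e-09
685,3.74269962769261e-09
690,2.74393728151248e-09
695,2.02070473894686e-09
700,1.49461555755215e-09
705,1.11023202581967e-09
710,8.28164101301988e-10
715,6.20296491428486e-10
720,4.66471861928969e-10
725,3.52175168871672e-10
730,2.66909540706710e-10
735,2.03052077392409e-10
740,1.55044210857687e-10
745,1.18816333712218e-10
750,9.13771840456595e-11
755,7.05195954189422e-11
760,5.46087788684892e-11
765,4.24293815290710e-11
770,3.30745729497501e-11
775,2.58653018850639e-11
780,2.02912957169245e-11
785,1.59677886146199e-11
790,1.26036705028517e-11
795,9.97795924294787e-12
800,7.92236043022481e-12
805,6.30829543765019e-12
810,5.03722049672456e-12
815,4.03337802300115e-12
820,3.23835151603430e-12
825,2.60696225831904e-12
830,2.10416749420959e-12
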