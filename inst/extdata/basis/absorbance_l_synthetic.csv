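# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,value
390,2.34482304387818e-01
395,2.23746149530198e-01
400,2.12248401210836e-01
405,2.00522996359461e-01
410,1.89130253727704e-01
415,1.78642431394758e-01
420,1.69630686262249e-01
425,1.62653763007331e-01
430,1.58248405636922e-01
435,1.56921153342750e-01
440,1.59140897814660e-01
445,1.65331387930113e-01
450,1.75862814776727e-01
455,1.91041732642472e-01
460,2.11098890230111e-01
465,2.36175051670832e-01
470,2.66305526938084e-01
475,3.01404802724073e-01
480,3.41253217080167e-01
485,3.85487879919874e-01
490,4.33599854937881e-01
495,4.84938916392371e-01
500,5.38726040062378e-01
505,5.94072396794155e-01
510,6.50002321295081e-01
515,7.05476891818614e-01
520,7.59414668170970e-01
525,8.10706930125659e-01
530,8.58226386091968e-01
535,9.00830575710074e-01
540,9.37363752064341e-01
545,9.66663488343063e-01
550,9.87580065418393e-01
555,9.99017109489603e-01
560,1.00000000000000e+00
565,9.89773317101742e-01
570,9.67919745746148e-01
575,9.34481673192044e-01
580,8.90056763071098e-01
585,8.35835411546561e-01
590,7.73555917046230e-01
595,7.05372887796917e-01
600,6.33659809919296e-01
605,5.60787123355694e-01
610,4.88923197034006e-01
615,4.19894907872709e-01
620,3.55122900682969e-01
625,2.95623815521185e-01
630,2.42056012095723e-01
635,1.94780278426785e-01
640,1.53912236764333e-01
645,1.19355584780505e-01
650,9.08199344446822e-02
655,6.78374261192489e-02
660,4.97931330027866e-02
665,3.59752603740215e-02
670,2.56385304442475e-02
675,1.80663213261746e-02
680,1.26180493282131e-02
685,8.75534348365469e-03
690,6.04826209968629e-03
695,4.16737010328800e-03
700,2.86838619023233e-03
705,1.97471778977941e-03
710,1.36113839579844e-03
715,9.40097572788861e-04
720,6.51001360455726e-04
725,4.52199442668652e-04
730,3.15185916888797e-04
735,2.20496182559829e-04
740,1.54849485496182e-04
745,1.09180467606301e-04
750,7.72928690647325e-05
755,5.49428448932770e-05
760,3.92163004466278e-05
765,2.81062990749439e-05
770,2.02261597484225e-05
775,1.46144366737099e-05
780,1.06021024268314e-05
785,7.72187541926266e-06
790,5.64614526836027e-06
795,4.14434506023273e-06
800,3.05358154318193e-06
805,2.25832999197696e-06
810,1.67634611532738e-06
815,1.24885603288702e-06
820,9.33700170989363e-07
825,7.00523949778233e-07
830,5.27391772932306e-07
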