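# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,value
390,5.15115540384805e-02
395,8.58305886192276e-02
400,1.34707254313741e-01
405,1.99542304168142e-01
410,2.79783289066315e-01
415,3.72761861475714e-01
420,4.74223161578254e-01
425,5.79309273566662e-01
430,6.83373243435722e-01
435,7.81992493080969e-01
440,8.70104238339871e-01
445,9.41044847748229e-01
450,9.86768057664002e-01
455,1.00000000000000e+00
460,9.77588320340985e-01
465,9.22828200626165e-01
470,8.44573079043602e-01
475,7.53069868447808e-01
480,6.55314127525140e-01
485,5.53576647975470e-01
490,4.48215519555728e-01
495,3.41999064582574e-01
500,2.41809427927089e-01
505,1.56222047265601e-01
510,9.12674753971459e-02
515,4.78728296299979e-02
520,2.24413593545573e-02
525,9.37534339866630e-03
530,3.48574452985795e-03
535,1.15307983243813e-03
540,3.39651787468589e-04
545,8.92698774120327e-05
550,2.10104298380338e-05
555,4.45342191148856e-06
560,8.57317660241391e-07
565,1.51650654125749e-07
570,2.50123801268441e-08
575,3.90758159866317e-09
580,5.85900053763285e-10
585,8.48765208457157e-11
590,1.18633145401051e-11
595,1.58831389993170e-12
600,2.01827887534808e-13
605,2.41438872319874e-14
610,2.70315652745962e-15
615,2.82215049422055e-16
620,2.74179169626842e-17
625,2.47609186706586e-18
630,2.07754915745435e-19
635,1.61914616574211e-20
640,1.17200015423595e-21
645,7.87877815786893e-23
650,4.91895937629535e-24
655,2.85212527627496e-25
660,1.53583446407534e-26
665,7.68069890745674e-28
670,3.56728608801113e-29
675,1.53870915050716e-30
680,6.16392341540898e-32
685,2.29319478175670e-33
690,7.92335002755871e-35
695,2.54250863581088e-36
700,7.57711154106402e-38
705,2.09717709042486e-39
710,5.39088428930309e-41
715,1.28701237577418e-42
720,2.85370416614889e-44
725,5.87687238856657e-46
730,1.12409953724184e-47
735,1.99709198853775e-49
740,3.29567637805845e-51
745,5.05206932413510e-53
750,7.19460021142376e-55
755,9.51927983189999e-57
760,1.17038156725084e-58
765,1.33742321344321e-60
770,1.42088041453451e-62
775,1.40402830753553e-64
780,1.29116561198774e-66
785,1.10596525029255e-68
790,8.83429495922774e-71
795,6.59176138751873e-73
800,4.60515401944799e-75
805,3.02193453743337e-77
810,1.87050838206194e-79
815,1.09796746213905e-81
820,6.15053666890369e-84
825,3.31012072458398e-86
830,1.72198917884755e-88
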