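# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,value
390,2.15716198831760e-01
395,2.04914283875670e-01
400,1.95138050566649e-01
405,1.87153074152578e-01
410,1.81707982931647e-01
415,1.79514834763101e-01
420,1.81231329879964e-01
425,1.87444158935588e-01
430,1.98652567930544e-01
435,2.15251302572325e-01
440,2.37512514054925e-01
445,2.65566937371799e-01
450,2.99385571581603e-01
455,3.38763981547635e-01
460,3.83311916332294e-01
465,4.32450916474177e-01
470,4.85421783854344e-01
475,5.41302249027531e-01
480,5.99033191616789e-01
485,6.57449869859550e-01
490,7.15313392515572e-01
495,7.71337603141361e-01
500,8.24207859880502e-01
505,8.72590783486184e-01
510,9.15137545772574e-01
515,9.50487125536143e-01
520,9.77279439315584e-01
525,9.94190361309037e-01
530,1.00000000000000e+00
535,9.93700557264931e-01
540,9.74639456500386e-01
545,9.42677860701875e-01
550,8.98328377749813e-01
555,8.42826568514431e-01
560,7.78097456061413e-01
565,7.06603799649511e-01
570,6.31100034003181e-01
575,5.54347933257434e-01
580,4.78861077731268e-01
585,4.06730077328299e-01
590,3.39548212562855e-01
595,2.78423631799656e-01
600,2.24042602275113e-01
605,1.76743921141888e-01
610,1.36575925580789e-01
615,1.03328452007883e-01
620,7.65528519889270e-02
625,5.55927937469849e-02
630,3.96413448178840e-02
635,2.78214279382260e-02
640,1.92710624545444e-02
645,1.32121128417084e-02
650,8.99038094504748e-03
655,6.08707506605854e-03
660,4.10961417145393e-03
665,2.77162460312599e-03
670,1.86998225854609e-03
675,1.26358800798437e-03
680,8.55894964813710e-04
685,5.81529320266199e-04
690,3.96527882712074e-04
695,2.71445703170441e-04
700,1.86599221003422e-04
705,1.28833718406847e-04
710,8.93491345553095e-05
715,6.22472108071416e-05
720,4.35642465750371e-05
725,3.06282036639730e-05
730,2.16314308870667e-05
735,1.53463879921887e-05
740,1.09361442504024e-05
745,7.82772907212034e-06
750,5.62722989385019e-06
755,4.06268246734084e-06
760,2.94551532035452e-06
765,2.14442054957999e-06
770,1.56757589692268e-06
775,1.15050009660393e-06
780,8.47722627971103e-07
785,6.27046413132908e-07
790,4.65580156502928e-07
795,3.46983282033432e-07
800,2.59545111355434e-07
805,1.94840286211906e-07
810,1.46783816866847e-07
815,1.10964370788359e-07
820,8.41720478845803e-08
825,6.40626279267399e-08
830,4.89179490030966e-08
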