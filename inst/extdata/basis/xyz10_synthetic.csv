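# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()
wavelength_nm,x,y,z
390,2.03250587844020e-02,3.11463668845470e-03,9.34997343470016e-02
395,3.46758500362670e-02,4.80830584285533e-03,1.60633360220534e-01
400,5.54343872682917e-02,7.00812429666738e-03,2.58699101192263e-01
405,8.34319240513744e-02,9.71909027980732e-03,3.92441689694785e-01
410,1.18766116655834e-01,1.29319042694326e-02,5.63427207110043e-01
415,1.60613309759310e-01,1.66548532700400e-02,7.69070147071121e-01
420,2.07174805672877e-01,2.09503406574072e-02,1.00222682894766e+00
425,2.55731341048301e-01,2.59641911728314e-02,1.25125329412648e+00
430,3.02784008542344e-01,3.19408021810318e-02,1.50045051235438e+00
435,3.44319383875617e-01,3.92261035023209e-02,1.73111557903870e+00
440,3.76255879113398e-01,4.82674943344859e-02,1.92353416705410e+00
445,3.95019121329380e-01,5.96201304658679e-02,2.05972517993474e+00
450,3.98033532595824e-01,7.39582567332269e-02,2.12589711629556e+00
455,3.83937153968105e-01,9.20701618247454e-02,2.11354169726529e+00
460,3.52625402970758e-01,1.14800053547291e-01,2.01950203481268e+00
465,3.05508233810853e-01,1.42916228456580e-01,1.84689858442437e+00
470,2.46140577835499e-01,1.76947391946345e-01,1.60801968497836e+00
475,1.80644524504646e-01,2.17097506951053e-01,1.32674190522011e+00
480,1.16947230201281e-01,2.63321143128356e-01,1.03568191520615e+00
485,6.27224145491935e-02,3.15470692005167e-01,7.66924233255627e-01
490,2.33229576394791e-02,3.73280464800712e-01,5.42099641528459e-01
495,1.04946442578056e-03,4.36074303378998e-01,3.68675088186935e-01
500,0.00000000000000e+00,5.02421043923917e-01,2.43108629083213e-01
505,5.74916002733125e-03,5.70134044823645e-01,1.56491146640809e-01
510,2.87551491374413e-02,6.36754512481219e-01,9.89281812867149e-02
515,6.23048979687785e-02,7.00203158929775e-01,6.17609928452735e-02
520,1.04253311009897e-01,7.59135590672859e-01,3.82739865899388e-02
525,1.53022906869156e-01,8.12841711108468e-01,2.36481235309278e-02
530,2.07652725924338e-01,8.60902466514397e-01,1.46173123259737e-02
535,2.67681185793189e-01,9.02893822594504e-01,9.06043228265350e-03
540,3.32950601328196e-01,9.38263241171656e-01,5.64042456877022e-03
545,4.03387734409221e-01,9.66343478953893e-01,3.52998862465326e-03
550,4.78771835993897e-01,9.86424225446184e-01,2.22222817970561e-03
555,5.58491622644691e-01,9.97831586977366e-01,1.40770959183216e-03
560,6.41311910796013e-01,1.00000000000000e+00,8.97509219380633e-04
565,7.25197663669264e-01,9.92534652904853e-01,5.75992916912101e-04
570,8.07257838882960e-01,9.75262123458419e-01,3.72109022507917e-04
575,8.83860104820103e-01,9.48265788988844e-01,2.41991643374059e-04
580,9.50927784872858e-01,9.11905927520798e-01,1.58414673517889e-04
585,1.00437531677624e+00,8.66829339156475e-01,1.04383666818550e-04
590,1.04059248734673e+00,8.13973843082728e-01,6.92279361246672e-05
595,1.05687322165715e+00,7.54566430517103e-01,4.62068065396718e-05
600,1.05170918621415e+00,6.90103969421628e-01,3.10360397708675e-05
605,1.02491956896210e+00,6.22300451263775e-01,2.09758520404392e-05
610,9.77639193589724e-01,5.52991617342288e-01,1.42633353624395e-05
615,9.12210079811751e-01,4.84005817014857e-01,9.75718688495635e-06
620,8.32007940760412e-01,4.17029543717477e-01,6.71402954191747e-06
625,7.41205279348332e-01,3.53503434972499e-01,4.64675282638000e-06
630,6.44459854439102e-01,2.94571637990633e-01,3.23426839451864e-06
635,5.46534437827050e-01,2.41080738641939e-01,2.26368115858035e-06
640,4.51883591460730e-01,1.93602023120553e-01,1.59301547823505e-06
645,3.64263142148004e-01,1.52448290261142e-01,1.12705086940316e-06
650,2.86423543453871e-01,1.17674099547108e-01,8.01566576880304e-07
655,2.19943397692402e-01,8.90716251305010e-02,5.73010568885502e-07
660,1.65239275505288e-01,6.61855363663395e-02,4.11687512391402e-07
665,1.21746805307050e-01,4.83622257420034e-02,2.97242299513512e-07
670,8.82185630767400e-02,3.48290923794998e-02,2.15649266811613e-07
675,6.30544286104429e-02,2.47837284219307e-02,1.57194456973678e-07
680,4.45867752955120e-02,1.74703470381901e-02,1.15116236999091e-07
685,3.12771275902382e-02,1.22297028372546e-02,8.46847385941904e-08
690,2.18193179723986e-02,8.52067441537240e-03,6.25752911739129e-08
695,1.51690729827514e-02,5.91982365441270e-03,4.64398251565585e-08
700,1.05277596518335e-02,4.10786424641542e-03,3.46122547750079e-08
705,7.30438863981947e-03,2.85076636800450e-03,2.59049858737205e-08
710,5.07210888855424e-03,1.98059380711663e-03,1.94676902975741e-08
715,3.52800502024130e-03,1.37869714838339e-03,1.46888281221399e-08
720,2.45978513278985e-03,9.62170228207947e-04,1.11267089481744e-08
725,1.71993955339457e-03,6.73516862313608e-04,8.46094849555685e-09
730,1.20653987492476e-03,4.73053157866125e-04,6.45818731128402e-09
735,8.49381643766240e-04,3.33461983336749e-04,4.94776493266295e-09
740,6.00181266946625e-04,2.35958311011654e-04,3.80436776778692e-09
745,4.25734889600386e-04,1.67621354631196e-04,2.93561999082982e-09
750,3.03187604514506e-04,1.19553332208402e-04,2.27316331391063e-09
755,2.16781007605088e-04,8.56151317485376e-05,1.76622636809655e-09
760,1.55624713839704e-04,6.15605760550862e-05,1.37694827631041e-09
765,1.12171891832938e-04,4.44443124070183e-05,1.07699797045836e-09
770,8.11766523378833e-05,3.22168087072177e-05,8.45110598136062e-10
775,5.89804278394146e-05,2.34470435218534e-05,6.65249229058757e-10
780,4.30227734996198e-05,1.71322968615494e-05,5.25293609790925e-10
785,3.15052977405273e-05,1.25673853761919e-05,4.16045845996988e-10
790,2.31601968196682e-05,9.25452218661253e-06,3.30503019810597e-10
795,1.70903734721643e-05,6.84099447260567e-06,2.63321962572876e-10
800,1.26586552085458e-05,5.07593557221121e-06,2.10396781101841e-10
805,9.41077985579645e-06,3.78024018383559e-06,1.68585321383832e-10
810,7.02167208145833e-06,2.82555362279713e-06,1.35458108646691e-10
815,5.25783541235650e-06,2.11954599925527e-06,1.09136501381434e-10
820,3.95093160938788e-06,1.59555409132676e-06,8.81675778749811e-11
825,2.97915265952773e-06,1.20526899852410e-06,7.14112632669872e-11
830,2.25403958268956e-06,9.13555195835737e-07,5.79891470941810e-11
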