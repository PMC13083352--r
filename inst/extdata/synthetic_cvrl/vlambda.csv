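"wavelength","vlambda"
390,0.00106306754409155
392,0.0012537396572986
394,0.00147563901662293
396,0.00173332163621046
398,0.00203190991134982
400,0.00237714679578477
402,0.00277545261084023
404,0.00323398419766033
406,0.003760696038874
408,0.00436440288309461
410,0.00505484330530486
412,0.00584274352909801
414,0.00673988072392617
416,0.00775914487321698
418,0.00891459818903031
420,0.0102215309277189
422,0.0116965123410248
424,0.0133574353806933
426,0.0152235536648282
428,0.0173155091139167
430,0.0196553485770686
432,0.0222665276980489
434,0.0251739002198378
436,0.0284036908994716
438,0.0319834502055828
440,0.0359419890030409
442,0.0403092914959129
444,0.0451164048048208
446,0.0503953037005057
448,0.0561787292043053
450,0.0625
452,0.0693927958809915
454,0.0768909127821182
456,0.0850279893156716
458,0.0938372051444082
460,0.103350951977454
462,0.113600478463718
464,0.124615510776262
466,0.136423851223364
468,0.149050957779818
470,0.162519507996363
472,0.176848951306037
474,0.192055054292641
476,0.208149444006845
478,0.22513915489754
480,0.243026185357233
482,0.261807070248259
484,0.281472476068877
486,0.302006825623277
488,0.323387959166324
490,0.345586838992686
492,0.368567304322775
494,0.392285883098245
496,0.416691666933284
498,0.441726254972701
500,0.467323771784319
502,0.493410963664766
504,0.519907376870347
506,0.546725620307234
508,0.573771714139334
510,0.600945524612327
512,0.628141284165329
514,0.655248194626736
516,0.682151109989098
518,0.708731293952198
520,0.7348672461378
522,0.760435589638272
524,0.78531201138941
526,0.809372245779399
528,0.832493090944542
530,0.854553446379869
532,0.875435359828803
534,0.895025070927972
536,0.913214038785023
538,0.929899940569734
540,0.944987628308607
542,0.958390031393329
544,0.970028992842721
546,0.979836028090322
548,0.987752995995838
550,0.993732672884396
552,0.997739221685099
554,0.999748549648669
556,0.999748549648669
558,0.997739221685099
560,0.993732672884396
562,0.987752995995838
564,0.979836028090322
566,0.970028992842721
568,0.958390031393329
570,0.944987628308607
572,0.929899940569734
574,0.913214038785023
576,0.895025070927972
578,0.875435359828803
580,0.854553446379869
582,0.832493090944542
584,0.809372245779399
586,0.78531201138941
588,0.760435589638272
590,0.7348672461378
592,0.708731293952198
594,0.682151109989098
596,0.655248194626736
598,0.628141284165329
600,0.600945524612327
602,0.573771714139334
604,0.546725620307234
606,0.519907376870347
608,0.493410963664766
610,0.467323771784319
612,0.441726254972701
614,0.416691666933284
616,0.392285883098245
618,0.368567304322775
620,0.345586838992686
622,0.323387959166324
624,0.302006825623277
626,0.281472476068877
628,0.261807070248259
630,0.243026185357233
632,0.22513915489754
634,0.208149444006845
636,0.192055054292641
638,0.176848951306037
640,0.162519507996363
642,0.149050957779818
644,0.136423851223364
646,0.124615510776262
648,0.113600478463718
650,0.103350951977454
652,0.0938372051444082
654,0.0850279893156716
656,0.0768909127821182
658,0.0693927958809915
660,0.0625
662,0.0561787292043053
664,0.0503953037005057
666,0.0451164048048208
668,0.0403092914959129
670,0.0359419890030409
672,0.0319834502055828
674,0.0284036908994716
676,0.0251739002198378
678,0.0222665276980489
680,0.0196553485770686
682,0.0173155091139167
684,0.0152235536648282
686,0.0133574353806933
688,0.0116965123410248
690,0.0102215309277189
692,0.00891459818903031
694,0.00775914487321698
696,0.00673988072392617
698,0.00584274352909801
700,0.00505484330530486
702,0.00436440288309461
704,0.003760696038874
706,0.00323398419766033
708,0.00277545261084023
710,0.00237714679578477
712,0.00203190991134982
714,0.00173332163621046
716,0.00147563901662293
718,0.0012537396572986
720,0.00106306754409155
722,0.000899581710405837
724,0.000759707890695318
726,0.00064029324406379
728,0.000538564178550099
730,0.000452087261859028
732,0.00037873316664658
734,0.000316643567492494
736,0.000264200881854007
738,0.00022000072802527
740,0.000182826958848014
742,0.000151629120054006
744,0.000125502176105477
746,0.000103668343694878
748,8.54608731592914e-05
750,7.03096204811093e-05
752,5.77282568480192e-05
754,4.73029685350691e-05
756,3.86825067948355e-05
758,3.15694551850864e-05
760,2.57125900540434e-05
762,2.09002185073741e-05
764,1.69543869008414e-05
766,1.37258615744621e-05
768,1.10897920352693e-05
770,8.94197500148556e-06
772,7.19564556094348e-06
774,5.7787291125599e-06
776,4.63149471193014e-06
778,3.70455690701786e-06
780,2.95717911716979e-06
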