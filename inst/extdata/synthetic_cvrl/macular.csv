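"wavelength","macular"
390,0.0229646014418062
392,0.0284036908994716
394,0.0349152230647569
396,0.042655893356044
398,0.0517925675022093
400,0.0625
402,0.0749577896740018
404,0.0893465328308966
406,0.105843164045316
408,0.124615510776262
410,0.145816129947015
412,0.169575540930959
414,0.195995018116067
416,0.22513915489754
418,0.257028456664017
420,0.291632259894029
422,0.328862304548564
424,0.368567304322775
426,0.410528861150158
428,0.454459054391546
430,0.5
432,0.546725620307234
434,0.594145791824056
436,0.641712948781452
438,0.688831117541916
440,0.7348672461378
442,0.7791645796605
444,0.821057722300316
446,0.859888927061611
448,0.895025070927972
450,0.92587471228729
452,0.951904593453771
454,0.972654947412286
456,0.987752995995838
458,0.996924086210092
460,1
462,0.996924086210092
464,0.987752995995838
466,0.972654947412286
468,0.951904593453771
470,0.92587471228729
472,0.895025070927972
474,0.859888927061611
476,0.821057722300316
478,0.7791645796605
480,0.7348672461378
482,0.688831117541916
484,0.641712948781452
486,0.594145791824056
488,0.546725620307234
490,0.5
492,0.454459054391546
494,0.410528861150158
496,0.368567304322775
498,0.328862304548564
500,0.291632259894029
502,0.257028456664017
504,0.22513915489754
506,0.195995018116067
508,0.169575540930959
510,0.145816129947015
512,0.124615510776262
514,0.105843164045316
516,0.0893465328308966
518,0.0749577896740018
520,0.0625
522,0.0517925675022093
524,0.042655893356044
526,0.0349152230647569
528,0.0284036908994716
530,0.0229646014418062
532,0.0184530103348364
534,0.0147366821088123
536,0.0116965123410248
538,0.00922650516741822
540,0.00723339618974446
542,0.0056360061017001
544,0.00436440288309461
546,0.00335894112133442
548,0.00256923675428566
550,0.001953125
552,0.00147563901662293
554,0.00110803734535529
556,0.000826899719104031
558,0.000613303535821927
560,0.000452087261859029
562,0.000331202228380779
564,0.000241150633788047
566,0.000174504946935345
568,0.000125502176105477
570,8.97054743820557e-05
572,6.37251426016939e-05
574,4.49911260159638e-05
576,3.15694551850864e-05
578,2.2015648834766e-05
580,1.52587890625e-05
582,1.05107287222583e-05
584,7.19564556094352e-06
586,4.89588126206553e-06
588,3.31067209172696e-06
590,2.22497756877159e-06
592,1.48613849575138e-06
594,9.86545474533948e-07
596,6.50877278992373e-07
598,4.26781211341844e-07
600,2.78122196096449e-07
602,1.80131715896354e-07
604,1.15949505259071e-07
606,7.41774315686155e-08
608,4.71627218479616e-08
610,2.98023223876953e-08
612,1.87165385687844e-08
614,1.16822134325544e-08
616,7.24684407869198e-09
618,4.46783242666733e-09
620,2.73759382269458e-09
622,1.66711410680409e-09
624,1.00898757556122e-09
626,6.06918657247973e-10
628,3.62826781189303e-10
630,2.15572005204691e-10
632,1.27294478078195e-10
634,7.47052194529043e-11
636,4.35729039498597e-11
638,2.52584235513836e-11
640,1.45519152283669e-11
642,8.33217242242576e-12
644,4.74155200974978e-12
646,2.68168008422636e-12
648,1.50736210350324e-12
650,8.42078145330828e-13
652,4.67532039081593e-13
654,2.57985048311598e-13
656,1.41482222687942e-13
658,7.71140280134931e-14
660,4.17723666792997e-14
662,2.24889382591064e-14
664,1.20329746147622e-14
666,6.39883964190464e-15
668,3.38184447007627e-15
670,1.77635683940027e-15
672,9.27322873055435e-16
674,4.81122768192871e-16
676,2.48087581161065e-16
678,1.27138861426175e-16
680,6.47553699315642e-17
682,3.27791311158105e-17
684,1.64908584516803e-17
686,8.24542922584014e-18
688,4.09739138947629e-18
690,2.02360531036138e-18
692,9.93272354891997e-19
694,4.84546056955211e-19
696,2.34923226656675e-19
698,1.13198592902275e-19
700,5.42101086242753e-20
702,2.58014257055378e-20
704,1.22048180425732e-20
706,5.73776942003362e-21
708,2.68089035261949e-21
710,1.2449135386735e-21
712,5.74544280867972e-22
714,2.63531175792109e-22
716,1.20133649702928e-22
718,5.4427892794087e-23
720,2.45076995730295e-23
722,1.09675027743159e-23
724,4.87794765690769e-24
726,2.15620821552411e-24
728,9.4725833405685e-25
730,4.13590306276519e-25
732,1.79471893711877e-25
734,7.74010259438643e-26
736,3.31757818785156e-26
738,1.41325260470054e-26
740,5.9833250910716e-27
742,2.51761654016875e-27
744,1.05283604273639e-27
746,4.37578608573749e-28
748,1.80748873637822e-28
750,7.42026292487084e-29
752,3.02752101455867e-29
754,1.22766313965338e-29
756,4.94760983711526e-30
758,1.98169060328957e-30
760,7.8886090522101e-31
762,3.12096713182919e-31
764,1.22716266565077e-31
766,4.79555913927102e-32
768,1.86251828869218e-32
770,7.18929026661426e-33
772,2.75800893612405e-33
774,1.05154895768312e-33
776,3.98462543914265e-34
778,1.50061639557406e-34
780,5.6166330207924e-35
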