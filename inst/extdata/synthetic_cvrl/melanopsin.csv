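"wavelength","mel"
390,0.105843164045316
392,0.116823304168127
394,0.128656834234944
396,0.141375104919157
398,0.155006433443983
400,0.169575540930959
402,0.185102976578532
404,0.201604535409772
406,0.219090677073168
408,0.237565953856868
410,0.257028456664017
412,0.277469288174987
414,0.298872072771614
416,0.321212513000902
418,0.34445800239461
420,0.368567304322775
422,0.39349030623243
424,0.41916785810013
426,0.445531703204768
428,0.472504508406106
430,0.5
432,0.527923209923279
434,0.556170835614679
436,0.584631715222822
438,0.613187418112145
440,0.641712948781452
442,0.67007756040974
444,0.698145672315369
446,0.725777883695677
448,0.752832074144024
450,0.7791645796605
452,0.804631431220942
454,0.829089641485436
456,0.852398523948498
458,0.874421027792036
460,0.895025070927972
462,0.914084853234186
464,0.931482131813429
466,0.947107440251894
468,0.960861234327189
470,0.972654947412286
472,0.982411939933184
474,0.990068328646777
476,0.995573683188195
478,0.99889157926368
480,1
482,0.99889157926368
484,0.995573683188195
486,0.990068328646777
488,0.982411939933184
490,0.972654947412286
492,0.960861234327189
494,0.947107440251894
496,0.931482131813429
498,0.914084853234186
500,0.895025070927972
502,0.874421027792036
504,0.852398523948498
506,0.829089641485436
508,0.804631431220942
510,0.7791645796605
512,0.752832074144024
514,0.725777883695677
516,0.698145672315369
518,0.67007756040974
520,0.641712948781452
522,0.613187418112145
524,0.584631715222822
526,0.556170835614679
528,0.527923209923279
530,0.5
532,0.472504508406106
534,0.445531703204768
536,0.41916785810013
538,0.39349030623243
540,0.368567304322775
542,0.34445800239461
544,0.321212513000902
546,0.298872072771614
548,0.277469288174987
550,0.257028456664017
552,0.237565953856868
554,0.219090677073168
556,0.201604535409772
558,0.185102976578532
560,0.169575540930959
562,0.155006433443983
564,0.141375104919157
566,0.128656834234944
568,0.116823304168127
570,0.105843164045316
572,0.0956825732789369
574,0.086305720664639
576,0.0776753151503949
578,0.0697530446149974
580,0.0625
582,0.0558770629112394
584,0.0498452555326885
586,0.0443660523674158
588,0.0394016539307894
590,0.0349152230647569
592,0.0308710850159249
594,0.0272348928229603
596,0.0239737598908372
598,0.0210563618924252
600,0.0184530103348364
602,0.0161357002628447
604,0.0140781346493977
606,0.0122557280491919
608,0.0106455920713419
610,0.00922650516741822
612,0.0079788691376968
614,0.00688465463742464
616,0.00592733782208442
618,0.00509183011158194
620,0.00436440288309461
622,0.00373260872567544
624,0.00318520071076017
626,0.00271205095510133
628,0.00230406957944172
630,0.001953125
632,0.00165196633261704
634,0.00139414854276774
636,0.00117396083969187
638,0.000986358690348941
640,0.000826899719104031
642,0.000691683662039505
644,0.000577296460331274
646,0.000480758504778989
648,0.0003994769827149
650,0.000331202228380779
652,0.000273987937607879
654,0.000226155076352682
656,0.000186259289393531
658,0.000153061599338109
660,0.000125502176105477
662,0.000102676952340008
664,8.38168599480731e-05
666,6.82694663405027e-05
668,5.54827952989155e-05
670,4.49911260159638e-05
672,3.64025742137294e-05
674,2.9388270817093e-05
676,2.36729660150875e-05
678,1.90268993138951e-05
680,1.52587890625e-05
682,1.22098076648874e-05
684,9.74842108105331e-06
686,7.76598310864271e-06
688,6.17298621357255e-06
690,4.89588126206553e-06
692,3.87438834823575e-06
694,3.05922998556887e-06
696,2.41022623244912e-06
698,1.89469886267968e-06
700,1.48613849575138e-06
702,1.16309470199257e-06
704,9.08254535025983e-07
706,7.07679763008262e-07
708,5.50177318343047e-07
710,4.26781211341844e-07
712,3.30327404795477e-07
714,2.55105970507436e-07
716,1.96577290442762e-07
718,1.51141166669099e-07
720,1.15949505259071e-07
722,8.87547762688608e-08
724,6.77877581388484e-08
726,5.16591805638242e-08
728,3.92808121693985e-08
730,2.98023223876953e-08
732,2.25609021609679e-08
734,1.70411743545029e-08
736,1.28433785022066e-08
738,9.65819005950974e-09
740,7.24684407869198e-09
742,5.42548779766022e-09
744,4.05289515339884e-09
746,3.02084645088931e-09
748,2.24661490872538e-09
750,1.66711410680409e-09
752,1.23435113386199e-09
754,9.1190336482743e-10
756,6.72195529954627e-10
758,4.94400755852717e-10
760,3.62826781189303e-10
762,2.65678401705922e-10
764,1.94110875272763e-10
766,1.41507738338992e-10
768,1.02931242644793e-10
770,7.47052194529043e-11
772,5.409926688347e-11
774,3.90902562972363e-11
776,2.81826845738824e-11
778,2.02736948783972e-11
780,1.45519152283669e-11
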