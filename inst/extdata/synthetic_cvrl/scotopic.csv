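"wavelength","rod"
390,0.0349152230647569
392,0.0394016539307894
394,0.0443660523674158
396,0.0498452555326885
398,0.0558770629112394
400,0.0625
402,0.0697530446149974
404,0.0776753151503949
406,0.086305720664639
408,0.0956825732789369
410,0.105843164045316
412,0.116823304168127
414,0.128656834234944
416,0.141375104919157
418,0.155006433443983
420,0.169575540930959
422,0.185102976578532
424,0.201604535409772
426,0.219090677073168
428,0.237565953856868
430,0.257028456664017
432,0.277469288174987
434,0.298872072771614
436,0.321212513000902
438,0.34445800239461
440,0.368567304322775
442,0.39349030623243
444,0.41916785810013
446,0.445531703204768
448,0.472504508406106
450,0.5
452,0.527923209923279
454,0.556170835614679
456,0.584631715222822
458,0.613187418112145
460,0.641712948781452
462,0.67007756040974
464,0.698145672315369
466,0.725777883695677
468,0.752832074144024
470,0.7791645796605
472,0.804631431220942
474,0.829089641485436
476,0.852398523948498
478,0.874421027792036
480,0.895025070927972
482,0.914084853234186
484,0.931482131813429
486,0.947107440251894
488,0.960861234327189
490,0.972654947412286
492,0.982411939933184
494,0.990068328646777
496,0.995573683188195
498,0.99889157926368
500,1
502,0.99889157926368
504,0.995573683188195
506,0.990068328646777
508,0.982411939933184
510,0.972654947412286
512,0.960861234327189
514,0.947107440251894
516,0.931482131813429
518,0.914084853234186
520,0.895025070927972
522,0.874421027792036
524,0.852398523948498
526,0.829089641485436
528,0.804631431220942
530,0.7791645796605
532,0.752832074144024
534,0.725777883695677
536,0.698145672315369
538,0.67007756040974
540,0.641712948781452
542,0.613187418112145
544,0.584631715222822
546,0.556170835614679
548,0.527923209923279
550,0.5
552,0.472504508406106
554,0.445531703204768
556,0.41916785810013
558,0.39349030623243
560,0.368567304322775
562,0.34445800239461
564,0.321212513000902
566,0.298872072771614
568,0.277469288174987
570,0.257028456664017
572,0.237565953856868
574,0.219090677073168
576,0.201604535409772
578,0.185102976578532
580,0.169575540930959
582,0.155006433443983
584,0.141375104919157
586,0.128656834234944
588,0.116823304168127
590,0.105843164045316
592,0.0956825732789369
594,0.086305720664639
596,0.0776753151503949
598,0.0697530446149974
600,0.0625
602,0.0558770629112394
604,0.0498452555326885
606,0.0443660523674158
608,0.0394016539307894
610,0.0349152230647569
612,0.0308710850159249
614,0.0272348928229603
616,0.0239737598908372
618,0.0210563618924252
620,0.0184530103348364
622,0.0161357002628447
624,0.0140781346493977
626,0.0122557280491919
628,0.0106455920713419
630,0.00922650516741822
632,0.0079788691376968
634,0.00688465463742464
636,0.00592733782208442
638,0.00509183011158194
640,0.00436440288309461
642,0.00373260872567544
644,0.00318520071076017
646,0.00271205095510133
648,0.00230406957944172
650,0.001953125
652,0.00165196633261704
654,0.00139414854276774
656,0.00117396083969187
658,0.000986358690348941
660,0.000826899719104031
662,0.000691683662039505
664,0.000577296460331274
666,0.000480758504778989
668,0.0003994769827149
670,0.000331202228380779
672,0.000273987937607879
674,0.000226155076352682
676,0.000186259289393531
678,0.000153061599338109
680,0.000125502176105477
682,0.000102676952340008
684,8.38168599480731e-05
686,6.82694663405027e-05
688,5.54827952989155e-05
690,4.49911260159638e-05
692,3.64025742137294e-05
694,2.9388270817093e-05
696,2.36729660150875e-05
698,1.90268993138951e-05
700,1.52587890625e-05
702,1.22098076648874e-05
704,9.74842108105331e-06
706,7.76598310864271e-06
708,6.17298621357255e-06
710,4.89588126206553e-06
712,3.87438834823575e-06
714,3.05922998556887e-06
716,2.41022623244912e-06
718,1.89469886267968e-06
720,1.48613849575138e-06
722,1.16309470199257e-06
724,9.08254535025983e-07
726,7.07679763008262e-07
728,5.50177318343047e-07
730,4.26781211341844e-07
732,3.30327404795477e-07
734,2.55105970507436e-07
736,1.96577290442762e-07
738,1.51141166669099e-07
740,1.15949505259071e-07
742,8.87547762688608e-08
744,6.77877581388484e-08
746,5.16591805638242e-08
748,3.92808121693985e-08
750,2.98023223876953e-08
752,2.25609021609679e-08
754,1.70411743545029e-08
756,1.28433785022066e-08
758,9.65819005950974e-09
760,7.24684407869198e-09
762,5.42548779766022e-09
764,4.05289515339884e-09
766,3.02084645088931e-09
768,2.24661490872538e-09
770,1.66711410680409e-09
772,1.23435113386199e-09
774,9.1190336482743e-10
776,6.72195529954627e-10
778,4.94400755852717e-10
780,3.62826781189303e-10
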