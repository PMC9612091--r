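# chromophore: deoxyhemoglobin
# units: absorption coefficient mm^-1 per uM
# conversion: mu_a = 2.303 * epsilon[cm^-1/M] * 1e-7 * 10  (per uM, per mm)
# source: synthetic monotone-spline approximation anchored at standard
#   molar extinction magnitudes (760-nm deoxy peak); not a literature
#   transcription
wavelength_nm,value
650,0.000863625
651,0.000853263
652,0.000842803
653,0.000832257
654,0.000821635
655,0.000810947
656,0.000800206
657,0.000789421
658,0.000778604
659,0.000767765
660,0.000756915
661,0.000746065
662,0.000735226
663,0.000724409
664,0.000713624
665,0.000702883
666,0.000692196
667,0.000681573
668,0.000671027
669,0.000660567
670,0.000650205
671,0.000639951
672,0.000629817
673,0.000619812
674,0.000609949
675,0.000600237
676,0.000590687
677,0.000581311
678,0.00057212
679,0.000563123
680,0.000554332
681,0.000545765
682,0.000537424
683,0.000529299
684,0.000521377
685,0.000513648
686,0.000506101
687,0.000498723
688,0.000491504
689,0.000484433
690,0.000477498
691,0.000470688
692,0.000463992
693,0.000457398
694,0.000450895
695,0.000444472
696,0.000438117
697,0.00043182
698,0.000425568
699,0.000419352
700,0.000413158
701,0.000406874
702,0.000400409
703,0.00039379
704,0.000387043
705,0.000380196
706,0.000373274
707,0.000366304
708,0.000359313
709,0.000352327
710,0.000345373
711,0.000338477
712,0.000331666
713,0.000324966
714,0.000318404
715,0.000312006
716,0.000305799
717,0.000299809
718,0.000294064
719,0.000288588
720,0.00028341
721,0.000278555
722,0.00027405
723,0.000269921
724,0.000266195
725,0.000262899
726,0.000260059
727,0.000257702
728,0.000255854
729,0.000254541
730,0.000253791
731,0.000253826
732,0.000254807
733,0.000256666
734,0.000259331
735,0.000262736
736,0.000266809
737,0.000271483
738,0.000276687
739,0.000282353
740,0.000288412
741,0.000294795
742,0.000301431
743,0.000308253
744,0.000315191
745,0.000322175
746,0.000329137
747,0.000336008
748,0.000342718
749,0.000349198
750,0.000355378
751,0.000361191
752,0.000366566
753,0.000371435
754,0.000375728
755,0.000379376
756,0.00038231
757,0.000384461
758,0.000385759
759,0.000386136
760,0.000385522
761,0.000383785
762,0.000380907
763,0.000376992
764,0.000372144
765,0.000366467
766,0.000360064
767,0.00035304
768,0.000345498
769,0.000337542
770,0.000329276
771,0.000320804
772,0.00031223
773,0.000303657
774,0.000295189
775,0.00028693
776,0.000278985
777,0.000271456
778,0.000264448
779,0.000258064
780,0.000252409
781,0.000247151
782,0.000241907
783,0.000236698
784,0.000231547
785,0.000226476
786,0.000221508
787,0.000216665
788,0.000211969
789,0.000207443
790,0.000203109
791,0.000198989
792,0.000195107
793,0.000191483
794,0.000188142
795,0.000185104
796,0.000182392
797,0.00018003
798,0.000178038
799,0.00017644
800,0.000175258
801,0.000174311
802,0.000173404
803,0.000172534
804,0.000171702
805,0.000170907
806,0.000170147
807,0.000169422
808,0.000168731
809,0.000168073
810,0.000167448
811,0.000166854
812,0.00016629
813,0.000165757
814,0.000165252
815,0.000164775
816,0.000164325
817,0.000163902
818,0.000163504
819,0.000163131
820,0.000162782
821,0.000162456
822,0.000162151
823,0.000161868
824,0.000161606
825,0.000161362
826,0.000161138
827,0.000160931
828,0.000160741
829,0.000160568
830,0.00016041
831,0.000160266
832,0.000160135
833,0.000160018
834,0.000159912
835,0.000159817
836,0.000159732
837,0.000159657
838,0.00015959
839,0.000159531
840,0.000159479
841,0.000159432
842,0.00015939
843,0.000159353
844,0.000159319
845,0.000159287
846,0.000159258
847,0.000159228
848,0.000159199
849,0.000159169
850,0.000159137
851,0.00015912
852,0.000159134
853,0.000159178
854,0.00015925
855,0.000159349
856,0.000159474
857,0.000159622
858,0.000159792
859,0.000159984
860,0.000160195
861,0.000160425
862,0.000160671
863,0.000160932
864,0.000161207
865,0.000161495
866,0.000161793
867,0.000162101
868,0.000162417
869,0.000162739
870,0.000163067
871,0.000163398
872,0.000163732
873,0.000164066
874,0.0001644
875,0.000164732
876,0.00016506
877,0.000165383
878,0.0001657
879,0.000166008
880,0.000166308
881,0.000166597
882,0.000166873
883,0.000167136
884,0.000167384
885,0.000167615
886,0.000167829
887,0.000168023
888,0.000168196
889,0.000168346
890,0.000168473
891,0.000168575
892,0.00016865
893,0.000168697
894,0.000168715
895,0.000168701
896,0.000168656
897,0.000168576
898,0.000168461
899,0.000168309
900,0.000168119
901,0.000167897
902,0.000167651
903,0.000167382
904,0.000167089
905,0.000166774
906,0.000166437
907,0.000166078
908,0.000165699
909,0.000165299
910,0.00016488
911,0.000164441
912,0.000163984
913,0.000163509
914,0.000163016
915,0.000162506
916,0.000161979
917,0.000161437
918,0.000160879
919,0.000160306
920,0.000159719
921,0.000159119
922,0.000158505
923,0.000157878
924,0.00015724
925,0.00015659
926,0.000155928
927,0.000155257
928,0.000154575
929,0.000153884
930,0.000153185
931,0.000152476
932,0.000151761
933,0.000151038
934,0.000150308
935,0.000149573
936,0.000148831
937,0.000148085
938,0.000147335
939,0.00014658
940,0.000145822
941,0.000145062
942,0.000144299
943,0.000143534
944,0.000142768
945,0.000142002
946,0.000141235
947,0.00014047
948,0.000139705
949,0.000138941
950,0.00013818
951,0.000137414
952,0.000136635
953,0.000135844
954,0.000135041
955,0.000134227
956,0.000133402
957,0.000132566
958,0.00013172
959,0.000130865
960,0.00013
961,0.000129126
962,0.000128243
963,0.000127352
964,0.000126453
965,0.000125547
966,0.000124633
967,0.000123713
968,0.000122787
969,0.000121855
970,0.000120917
971,0.000119974
972,0.000119026
973,0.000118074
974,0.000117117
975,0.000116158
976,0.000115195
977,0.000114229
978,0.00011326
979,0.00011229
980,0.000111318
981,0.000110344
982,0.00010937
983,0.000108395
984,0.00010742
985,0.000106446
986,0.000105472
987,0.000104499
988,0.000103527
989,0.000102557
990,0.00010159
991,0.000100625
992,9.96629e-05
993,9.87043e-05
994,9.77493e-05
995,9.67985e-05
996,9.58523e-05
997,9.49109e-05
998,9.39748e-05
999,9.30444e-05
1000,9.212e-05
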