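# chromophore: water
# units: absorption coefficient mm^-1 at volume fraction 1.0 (100%)
# source: synthetic monotone-spline approximation anchored at standard
#   pure-water absorption magnitudes (970-nm peak ~0.0485 mm^-1); not a
#   literature transcription
wavelength_nm,value
650,0.00034
651,0.000343369
652,0.000346495
653,0.000349396
654,0.000352093
655,0.000354606
656,0.000356954
657,0.000359158
658,0.000361237
659,0.000363212
660,0.000365103
661,0.000366928
662,0.000368709
663,0.000370465
664,0.000372216
665,0.000373981
666,0.000375782
667,0.000377638
668,0.000379568
669,0.000381593
670,0.000383732
671,0.000386006
672,0.000388434
673,0.000391037
674,0.000393834
675,0.000396845
676,0.00040009
677,0.000403589
678,0.000407363
679,0.00041143
680,0.00041581
681,0.000420525
682,0.000425593
683,0.000431035
684,0.00043687
685,0.000443118
686,0.0004498
687,0.000456935
688,0.000464543
689,0.000472645
690,0.000481259
691,0.000490406
692,0.000500106
693,0.000510379
694,0.000521245
695,0.000532723
696,0.000544834
697,0.000557597
698,0.000571032
699,0.00058516
700,6e-04
701,0.000616694
702,0.000636291
703,0.000658667
704,0.000683701
705,0.000711271
706,0.000741256
707,0.000773533
708,0.00080798
709,0.000844475
710,0.000882898
711,0.000923125
712,0.000965034
713,0.0010085
714,0.00105341
715,0.00109964
716,0.00114706
717,0.00119556
718,0.001245
719,0.00129528
720,0.00134626
721,0.00139783
722,0.00144986
723,0.00150223
724,0.00155483
725,0.00160752
726,0.00166018
727,0.00171271
728,0.00176496
729,0.00181682
730,0.00186817
731,0.00191889
732,0.00196885
733,0.00201794
734,0.00206602
735,0.00211299
736,0.00215871
737,0.00220307
738,0.00224594
739,0.0022872
740,0.00232672
741,0.0023644
742,0.0024001
743,0.00243371
744,0.00246509
745,0.00249414
746,0.00252073
747,0.00254473
748,0.00256602
749,0.00258448
750,0.0026
751,0.0026124
752,0.0026217
753,0.00262801
754,0.00263149
755,0.00263225
756,0.00263043
757,0.00262617
758,0.00261958
759,0.00261082
760,0.0026
761,0.00258726
762,0.00257274
763,0.00255655
764,0.00253885
765,0.00251975
766,0.00249939
767,0.00247791
768,0.00245542
769,0.00243208
770,0.002408
771,0.00238332
772,0.00235818
773,0.00233269
774,0.00230701
775,0.00228125
776,0.00225555
777,0.00223005
778,0.00220486
779,0.00218014
780,0.002156
781,0.00213258
782,0.00211002
783,0.00208843
784,0.00206797
785,0.00204875
786,0.00203091
787,0.00201459
788,0.0019999
789,0.001987
790,0.001976
791,0.00196704
792,0.00196026
793,0.00195577
794,0.00195373
795,0.00195425
796,0.00195747
797,0.00196353
798,0.00197254
799,0.00198466
800,0.002
801,0.00201811
802,0.00203839
803,0.00206079
804,0.00208523
805,0.00211165
806,0.00213999
807,0.00217018
808,0.00220215
809,0.00223585
810,0.0022712
811,0.00230815
812,0.00234662
813,0.00238655
814,0.00242788
815,0.00247055
816,0.00251448
817,0.00255962
818,0.00260589
819,0.00265324
820,0.0027016
821,0.0027509
822,0.00280108
823,0.00285208
824,0.00290382
825,0.00295625
826,0.0030093
827,0.0030629
828,0.003117
829,0.00317152
830,0.0032264
831,0.00328158
832,0.00333699
833,0.00339256
834,0.00344824
835,0.00350395
836,0.00355964
837,0.00361523
838,0.00367066
839,0.00372587
840,0.0037808
841,0.00383537
842,0.00388953
843,0.0039432
844,0.00399633
845,0.00404885
846,0.00410069
847,0.00415179
848,0.00420209
849,0.00425151
850,0.0043
851,0.00434575
852,0.00438717
853,0.00442456
854,0.0044582
855,0.00448835
856,0.00451531
857,0.00453935
858,0.00456076
859,0.00457982
860,0.0045968
861,0.00461199
862,0.00462567
863,0.00463812
864,0.00464962
865,0.00466045
866,0.00467089
867,0.00468123
868,0.00469174
869,0.0047027
870,0.0047144
871,0.00472711
872,0.00474113
873,0.00475672
874,0.00477416
875,0.00479375
876,0.00481576
877,0.00484046
878,0.00486815
879,0.00489911
880,0.0049336
881,0.00497192
882,0.00501434
883,0.00506115
884,0.00511263
885,0.00516905
886,0.0052307
887,0.00529786
888,0.00537081
889,0.00544983
890,0.0055352
891,0.0056272
892,0.00572612
893,0.00583223
894,0.00594581
895,0.00606715
896,0.00619652
897,0.00633422
898,0.00648051
899,0.00663567
900,0.0068
901,0.00697388
902,0.00715748
903,0.00735079
904,0.00755377
905,0.0077664
906,0.00798864
907,0.00822047
908,0.00846186
909,0.00871278
910,0.0089732
911,0.00924309
912,0.00952243
913,0.00981117
914,0.0101093
915,0.0104168
916,0.0107336
917,0.0110597
918,0.0113951
919,0.0117398
920,0.0120936
921,0.0124566
922,0.0128288
923,0.0132101
924,0.0136005
925,0.014
926,0.0144024
927,0.0148028
928,0.0152026
929,0.0156034
930,0.0160068
931,0.0164143
932,0.0168275
933,0.0172478
934,0.017677
935,0.0181164
936,0.0185677
937,0.0190324
938,0.0195121
939,0.0200083
940,0.0205226
941,0.0210565
942,0.0216115
943,0.0221893
944,0.0227913
945,0.0234192
946,0.0240744
947,0.0247586
948,0.0254732
949,0.0262198
950,0.027
951,0.027843
952,0.0287702
953,0.0297717
954,0.0308376
955,0.0319578
956,0.0331224
957,0.0343214
958,0.0355448
959,0.0367827
960,0.038025
961,0.0392618
962,0.0404832
963,0.0416791
964,0.0428396
965,0.0439547
966,0.0450144
967,0.0460088
968,0.0469278
969,0.0477615
970,0.0485
971,0.0491168
972,0.0495854
973,0.0498956
974,0.0500372
975,0.05
976,0.0498363
977,0.0496079
978,0.049319
979,0.0489736
980,0.048576
981,0.0481302
982,0.0476404
983,0.0471107
984,0.0465452
985,0.045948
986,0.0453233
987,0.0446753
988,0.0440079
989,0.0433255
990,0.042632
991,0.0419316
992,0.0412285
993,0.0405268
994,0.0398306
995,0.039144
996,0.0384712
997,0.0378162
998,0.0371833
999,0.0365765
1000,0.036
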