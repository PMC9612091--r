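# chromophore: oxyhemoglobin
# units: absorption coefficient mm^-1 per uM
# conversion: mu_a = 2.303 * epsilon[cm^-1/M] * 1e-7 * 10  (per uM, per mm)
# source: synthetic monotone-spline approximation anchored at standard
#   molar extinction magnitudes; not a literature transcription
wavelength_nm,value
650,8.47504e-05
651,8.41323e-05
652,8.34783e-05
653,8.27924e-05
654,8.20785e-05
655,8.13407e-05
656,8.05829e-05
657,7.98091e-05
658,7.90234e-05
659,7.82297e-05
660,7.7432e-05
661,7.66343e-05
662,7.58406e-05
663,7.50548e-05
664,7.42811e-05
665,7.35233e-05
666,7.27854e-05
667,7.20716e-05
668,7.13856e-05
669,7.07316e-05
670,7.01136e-05
671,6.95354e-05
672,6.90012e-05
673,6.85148e-05
674,6.80804e-05
675,6.77018e-05
676,6.73831e-05
677,6.71283e-05
678,6.69414e-05
679,6.68263e-05
680,6.6787e-05
681,6.6787e-05
682,6.6787e-05
683,6.6787e-05
684,6.6787e-05
685,6.6787e-05
686,6.6787e-05
687,6.6787e-05
688,6.6787e-05
689,6.6787e-05
690,6.6787e-05
691,6.6787e-05
692,6.6787e-05
693,6.6787e-05
694,6.6787e-05
695,6.6787e-05
696,6.6787e-05
697,6.6787e-05
698,6.6787e-05
699,6.6787e-05
700,6.6787e-05
701,6.68255e-05
702,6.6939e-05
703,6.71251e-05
704,6.73809e-05
705,6.77039e-05
706,6.80914e-05
707,6.85407e-05
708,6.90492e-05
709,6.96142e-05
710,7.0233e-05
711,7.0903e-05
712,7.16215e-05
713,7.23858e-05
714,7.31934e-05
715,7.40414e-05
716,7.49274e-05
717,7.58486e-05
718,7.68023e-05
719,7.77859e-05
720,7.87967e-05
721,7.98321e-05
722,8.08894e-05
723,8.1966e-05
724,8.30591e-05
725,8.41661e-05
726,8.52844e-05
727,8.64113e-05
728,8.75442e-05
729,8.86803e-05
730,8.9817e-05
731,9.09802e-05
732,9.21955e-05
733,9.34598e-05
734,9.47701e-05
735,9.61233e-05
736,9.75164e-05
737,9.89462e-05
738,0.00010041
739,0.000101904
740,0.000103426
741,0.000104972
742,0.00010654
743,0.000108127
744,0.000109729
745,0.000111343
746,0.000112966
747,0.000114596
748,0.000116229
749,0.000117862
750,0.000119492
751,0.000121116
752,0.00012273
753,0.000124333
754,0.000125921
755,0.00012749
756,0.000129038
757,0.000130562
758,0.000132058
759,0.000133524
760,0.000134956
761,0.000136368
762,0.000137777
763,0.000139182
764,0.000140583
765,0.00014198
766,0.000143372
767,0.000144761
768,0.000146146
769,0.000147526
770,0.000148902
771,0.000150274
772,0.000151641
773,0.000153004
774,0.000154362
775,0.000155716
776,0.000157065
777,0.00015841
778,0.00015975
779,0.000161085
780,0.000162415
781,0.000163741
782,0.000165061
783,0.000166377
784,0.000167687
785,0.000168993
786,0.000170293
787,0.000171588
788,0.000172878
789,0.000174162
790,0.000175441
791,0.000176715
792,0.000177983
793,0.000179246
794,0.000180503
795,0.000181754
796,0.000183
797,0.00018424
798,0.000185474
799,0.000186702
800,0.000187925
801,0.000189145
802,0.000190365
803,0.000191586
804,0.000192807
805,0.000194028
806,0.000195248
807,0.000196468
808,0.000197686
809,0.000198903
810,0.000200118
811,0.000201331
812,0.000202541
813,0.000203749
814,0.000204953
815,0.000206155
816,0.000207352
817,0.000208546
818,0.000209735
819,0.00021092
820,0.0002121
821,0.000213274
822,0.000214443
823,0.000215607
824,0.000216764
825,0.000217914
826,0.000219058
827,0.000220195
828,0.000221324
829,0.000222445
830,0.000223559
831,0.000224664
832,0.00022576
833,0.000226848
834,0.000227926
835,0.000228994
836,0.000230053
837,0.000231101
838,0.000232139
839,0.000233166
840,0.000234182
841,0.000235186
842,0.000236179
843,0.000237159
844,0.000238127
845,0.000239083
846,0.000240025
847,0.000240954
848,0.000241869
849,0.00024277
850,0.000243657
851,0.000244534
852,0.000245404
853,0.000246267
854,0.000247123
855,0.000247972
856,0.000248813
857,0.000249648
858,0.000250474
859,0.000251292
860,0.000252103
861,0.000252905
862,0.000253699
863,0.000254484
864,0.000255261
865,0.000256029
866,0.000256787
867,0.000257536
868,0.000258276
869,0.000259006
870,0.000259727
871,0.000260437
872,0.000261137
873,0.000261827
874,0.000262507
875,0.000263175
876,0.000263833
877,0.00026448
878,0.000265115
879,0.00026574
880,0.000266352
881,0.000266953
882,0.000267542
883,0.000268118
884,0.000268683
885,0.000269235
886,0.000269774
887,0.000270301
888,0.000270814
889,0.000271315
890,0.000271802
891,0.000272275
892,0.000272735
893,0.000273181
894,0.000273613
895,0.000274031
896,0.000274434
897,0.000274823
898,0.000275197
899,0.000275556
900,0.000275899
901,0.000276227
902,0.000276536
903,0.000276828
904,0.000277104
905,0.000277362
906,0.000277604
907,0.00027783
908,0.000278041
909,0.000278236
910,0.000278416
911,0.000278582
912,0.000278733
913,0.00027887
914,0.000278994
915,0.000279104
916,0.000279202
917,0.000279287
918,0.00027936
919,0.000279421
920,0.00027947
921,0.000279508
922,0.000279535
923,0.000279552
924,0.000279559
925,0.000279555
926,0.000279543
927,0.000279521
928,0.00027949
929,0.000279451
930,0.000279404
931,0.000279349
932,0.000279286
933,0.000279217
934,0.00027914
935,0.000279058
936,0.000278969
937,0.000278874
938,0.000278774
939,0.000278669
940,0.00027856
941,0.000278446
942,0.000278328
943,0.000278206
944,0.000278081
945,0.000277953
946,0.000277823
947,0.00027769
948,0.000277555
949,0.000277419
950,0.000277281
951,0.000277136
952,0.000276979
953,0.000276809
954,0.000276627
955,0.000276433
956,0.000276228
957,0.000276012
958,0.000275785
959,0.000275549
960,0.000275302
961,0.000275047
962,0.000274783
963,0.00027451
964,0.000274229
965,0.00027394
966,0.000273644
967,0.000273341
968,0.000273032
969,0.000272716
970,0.000272395
971,0.000272069
972,0.000271737
973,0.000271401
974,0.000271061
975,0.000270718
976,0.000270371
977,0.000270021
978,0.000269668
979,0.000269314
980,0.000268957
981,0.0002686
982,0.000268241
983,0.000267882
984,0.000267523
985,0.000267164
986,0.000266805
987,0.000266448
988,0.000266092
989,0.000265738
990,0.000265387
991,0.000265038
992,0.000264692
993,0.000264349
994,0.00026401
995,0.000263676
996,0.000263346
997,0.000263021
998,0.000262702
999,0.000262389
1000,0.000262081
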