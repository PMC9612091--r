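# chromophore: lipid
# units: absorption coefficient mm^-1 at volume fraction 1.0 (100%)
# source: synthetic monotone-spline approximation anchored at standard
#   soybean-oil absorption magnitudes (930-nm peak ~0.0105 mm^-1); not a
#   literature transcription
wavelength_nm,value
650,6e-04
651,0.000606
652,0.000612
653,0.000618
654,0.000624
655,0.00063
656,0.000636
657,0.000642
658,0.000648
659,0.000654
660,0.00066
661,0.000666
662,0.000672
663,0.000678
664,0.000684
665,0.00069
666,0.000696
667,0.000702
668,0.000708
669,0.000714
670,0.00072
671,0.000726
672,0.000732
673,0.000738
674,0.000744
675,0.00075
676,0.000756
677,0.000762
678,0.000768
679,0.000774
680,0.00078
681,0.000786
682,0.000792
683,0.000798
684,0.000804
685,0.00081
686,0.000816
687,0.000822
688,0.000828
689,0.000834
690,0.00084
691,0.000846
692,0.000852
693,0.000858
694,0.000864
695,0.00087
696,0.000876
697,0.000882
698,0.000888
699,0.000894
700,9e-04
701,0.000906078
702,0.000912307
703,0.000918677
704,0.000925178
705,0.0009318
706,0.000938534
707,0.000945371
708,0.000952301
709,0.000959314
710,0.0009664
711,0.00097355
712,0.000980755
713,0.000988005
714,0.00099529
715,0.0010026
716,0.00100993
717,0.00101726
718,0.00102459
719,0.00103191
720,0.0010392
721,0.00104646
722,0.00105368
723,0.00106085
724,0.00106796
725,0.001075
726,0.00108196
727,0.00108883
728,0.0010956
729,0.00110226
730,0.0011088
731,0.00111521
732,0.00112149
733,0.00112762
734,0.00113359
735,0.0011394
736,0.00114503
737,0.00115048
738,0.00115572
739,0.00116077
740,0.0011656
741,0.00117021
742,0.00117458
743,0.00117871
744,0.00118259
745,0.0011862
746,0.00118954
747,0.0011926
748,0.00119537
749,0.00119784
750,0.0012
751,0.00120174
752,0.00120299
753,0.00120376
754,0.00120407
755,0.00120395
756,0.00120342
757,0.00120249
758,0.0012012
759,0.00119956
760,0.0011976
761,0.00119533
762,0.00119278
763,0.00118997
764,0.00118692
765,0.00118365
766,0.00118019
767,0.00117655
768,0.00117276
769,0.00116883
770,0.0011648
771,0.00116068
772,0.00115649
773,0.00115226
774,0.00114801
775,0.00114375
776,0.00113951
777,0.00113532
778,0.00113119
779,0.00112714
780,0.0011232
781,0.00111939
782,0.00111572
783,0.00111223
784,0.00110893
785,0.00110585
786,0.001103
787,0.00110041
788,0.0010981
789,0.00109609
790,0.0010944
791,0.00109306
792,0.00109208
793,0.00109149
794,0.0010913
795,0.00109155
796,0.00109225
797,0.00109342
798,0.00109509
799,0.00109728
800,0.0011
801,0.00110311
802,0.00110645
803,0.00111001
804,0.0011138
805,0.0011178
806,0.00112202
807,0.00112646
808,0.00113112
809,0.00113599
810,0.00114107
811,0.00114636
812,0.00115186
813,0.00115757
814,0.00116348
815,0.0011696
816,0.00117592
817,0.00118244
818,0.00118916
819,0.00119608
820,0.0012032
821,0.00121051
822,0.00121801
823,0.00122571
824,0.00123359
825,0.00124167
826,0.00124993
827,0.00125837
828,0.001267
829,0.00127581
830,0.0012848
831,0.00129397
832,0.00130332
833,0.00131284
834,0.00132253
835,0.0013324
836,0.00134244
837,0.00135265
838,0.00136302
839,0.00137356
840,0.00138427
841,0.00139513
842,0.00140616
843,0.00141735
844,0.0014287
845,0.0014402
846,0.00145186
847,0.00146367
848,0.00147563
849,0.00148774
850,0.0015
851,0.00151168
852,0.00152215
853,0.0015316
854,0.00154017
855,0.00154803
856,0.00155536
857,0.00156231
858,0.00156906
859,0.00157577
860,0.00158259
861,0.00158971
862,0.00159728
863,0.00160547
864,0.00161445
865,0.00162438
866,0.00163542
867,0.00164775
868,0.00166152
869,0.00167691
870,0.00169407
871,0.00171318
872,0.00173441
873,0.0017579
874,0.00178384
875,0.00181238
876,0.0018437
877,0.00187796
878,0.00191531
879,0.00195594
880,0.002
881,0.00204571
882,0.0020915
883,0.00213788
884,0.00218533
885,0.00223437
886,0.0022855
887,0.00233921
888,0.002396
889,0.00245638
890,0.00252083
891,0.00258988
892,0.002664
893,0.00274371
894,0.0028295
895,0.00292188
896,0.00302133
897,0.00312838
898,0.0032435
899,0.00336721
900,0.0035
901,0.00364348
902,0.00379841
903,0.003964
904,0.00413948
905,0.00432407
906,0.004517
907,0.00471748
908,0.00492474
909,0.005138
910,0.00535648
911,0.00557941
912,0.005806
913,0.00603548
914,0.00626707
915,0.0065
916,0.00675526
917,0.00704874
918,0.007372
919,0.00771659
920,0.00807407
921,0.008436
922,0.00879393
923,0.00913941
924,0.009464
925,0.00975926
926,0.0100167
927,0.010228
928,0.0103846
929,0.0104781
930,0.0105
931,0.0104412
932,0.0103048
933,0.0101008
934,0.00983908
935,0.00952963
936,0.0091824
937,0.00880735
938,0.00841443
939,0.0080136
940,0.00761481
941,0.00722803
942,0.0068632
943,0.00653028
944,0.00623923
945,0.006
946,0.00579973
947,0.00561787
948,0.0054528
949,0.00530293
950,0.00516667
951,0.0050424
952,0.00492853
953,0.00482347
954,0.0047256
955,0.00463333
956,0.00454507
957,0.0044592
958,0.00437413
959,0.00428827
960,0.0042
961,0.00411221
962,0.0040287
963,0.00394924
964,0.0038736
965,0.00380156
966,0.0037329
967,0.00366739
968,0.0036048
969,0.00354491
970,0.0034875
971,0.00343234
972,0.0033792
973,0.00332786
974,0.0032781
975,0.00322969
976,0.0031824
977,0.00313601
978,0.0030903
979,0.00304504
980,0.003
981,0.00295646
982,0.0029157
983,0.00287749
984,0.0028416
985,0.00280781
986,0.0027759
987,0.00274564
988,0.0027168
989,0.00268916
990,0.0026625
991,0.00263659
992,0.0026112
993,0.00258611
994,0.0025611
995,0.00253594
996,0.0025104
997,0.00248426
998,0.0024573
999,0.00242929
1000,0.0024
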