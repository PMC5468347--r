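# SYNTHETIC pairwise interaction-energy predictor matrix (arbitrary units).
# Stand-in with hydrophobic-attraction structure: P = -0.8 h h' + deterministic ripple,
# h = standardized Kyte-Doolittle hydrophobicity. Replace with a published 20x20
# predictor matrix (same format: header of residue codes, then 20 rows x 20 values).
A C D E F G H I K L M N P Q R S T V W Y
-0.358213 -0.492647 0.743470 0.741317 -0.561239 0.080178 0.633446 -0.974056 0.721293 -0.890304 -0.529653 0.552671 0.140712 0.514894 0.710775 -0.051903 -0.069438 -1.067744 -0.009334 0.085685
-0.492647 -0.660153 0.960592 0.962598 -0.735694 0.101713 0.821748 -1.281236 0.927252 -1.182131 -0.715503 0.695173 0.157285 0.648771 0.910502 -0.076511 -0.088338 -1.379294 0.015572 0.151867
0.743470 0.960592 -0.640712 -0.635674 1.055094 0.167186 -0.625972 1.404428 -0.916828 1.105549 0.540162 -0.962044 -0.482399 -1.014111 -1.287495 -0.277335 -0.225640 1.131539 -0.204330 -0.270352
0.741317 0.962598 -0.635674 -0.629184 1.061198 0.171032 -0.626059 1.399141 -0.928012 1.088450 0.517830 -0.988273 -0.510664 -1.042202 -1.313088 -0.298225 -0.239973 1.125070 -0.202312 -0.259977
-0.561239 -0.735694 1.055094 1.061198 -0.807754 0.109155 0.893118 -1.432025 0.985410 -1.348145 -0.845454 0.699315 0.104558 0.647790 0.943795 -0.128988 -0.124381 -1.524238 0.032525 0.203912
0.080178 0.101713 0.167186 0.171032 0.109155 0.108997 0.092250 -0.019514 -0.007370 -0.126168 -0.163298 -0.163115 -0.208763 -0.207943 -0.197431 -0.208432 -0.176132 -0.171869 -0.080758 -0.026476
0.633446 0.821748 -0.625972 -0.626059 0.893118 0.092250 -0.621703 1.208005 -0.878862 0.946139 0.442206 -0.904508 -0.466469 -0.938763 -1.178417 -0.262508 -0.209652 1.018436 -0.178235 -0.231718
-0.974056 -1.281236 1.404428 1.399141 -1.432025 -0.019514 1.208005 -2.266883 1.459788 -2.016741 -1.194757 1.198883 0.333930 1.178255 1.629471 -0.012993 -0.036602 -2.201672 0.111413 0.322720
0.721293 0.927252 -0.916828 -0.928012 0.985410 -0.007370 -0.878862 1.459788 -1.123839 1.216672 0.624176 -1.035360 -0.459060 -1.040450 -1.342311 -0.202906 -0.160494 1.352631 -0.189665 -0.293670
-0.890304 -1.182131 1.105549 1.088450 -1.348145 -0.126168 0.946139 -2.016741 1.216672 -1.740756 -1.004025 1.079481 0.354573 1.090493 1.479023 0.058452 0.021835 -1.861466 0.102357 0.259501
-0.529653 -0.715503 0.540162 0.517830 -0.845454 -0.163298 0.442206 -1.194757 0.624176 -1.004025 -0.574489 0.602990 0.211819 0.629258 0.847408 0.052116 0.023115 -1.037989 0.042710 0.117449
0.552671 0.695173 -0.962044 -0.988273 0.699315 -0.163115 -0.904508 1.198883 -1.035360 1.079481 0.602990 -0.822381 -0.285024 -0.783026 -1.048893 -0.056702 -0.044964 1.256141 -0.144349 -0.275138
0.140712 0.157285 -0.482399 -0.510664 0.104558 -0.208763 -0.466469 0.333930 -0.459060 0.354573 0.211819 -0.285024 -0.065062 -0.235850 -0.330848 0.028561 0.018287 0.477727 -0.061842 -0.132568
0.514894 0.648771 -1.014111 -1.042202 0.647790 -0.207943 -0.938763 1.178255 -1.040450 1.090493 0.629258 -0.783026 -0.235850 -0.728061 -0.992513 -0.003180 0.001959 1.293625 -0.117978 -0.260254
0.710775 0.910502 -1.287495 -1.313088 0.943795 -0.197431 -1.178417 1.629471 -1.342311 1.479023 0.847408 -1.048893 -0.330848 -0.992513 -1.345292 -0.022478 -0.006390 1.726720 -0.140205 -0.316695
-0.051903 -0.076511 -0.277335 -0.298225 -0.128988 -0.208432 -0.262508 -0.012993 -0.202906 0.058452 0.052116 -0.056702 0.028561 -0.003180 -0.022478 0.076559 0.064892 0.178879 0.010854 -0.026432
-0.069438 -0.088338 -0.225640 -0.239973 -0.124381 -0.176132 -0.209652 -0.036602 -0.160494 0.021835 0.023115 -0.044964 0.018287 0.001959 -0.006390 0.064892 0.060618 0.140912 0.029662 0.006541
-1.067744 -1.379294 1.131539 1.125070 -1.524238 -0.171869 1.018436 -2.201672 1.352631 -1.861466 -1.037989 1.256141 0.477727 1.293625 1.726720 0.178879 0.140912 -1.918862 0.224561 0.390602
-0.009334 0.015572 -0.204330 -0.202312 0.032525 -0.080758 -0.178235 0.111413 -0.189665 0.102357 0.042710 -0.144349 -0.061842 -0.117978 -0.140205 0.010854 0.029662 0.224561 0.050955 0.048757
0.085685 0.151867 -0.270352 -0.259977 0.203912 -0.026476 -0.231718 0.322720 -0.293670 0.259501 0.117449 -0.275138 -0.132568 -0.260254 -0.316695 -0.026432 0.006541 0.390602 0.048757 0.046418
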