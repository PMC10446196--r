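zip,county
20601,County01
20602,County01
20603,County01
20604,County01
20605,County01
20606,County02
20607,County02
20608,County02
20609,County02
20610,County02
20611,County03
20612,County03
20613,County03
20614,County03
20615,County03
20616,County04
20617,County04
20618,County04
20619,County04
20620,County04
20621,County05
20622,County05
20623,County05
20624,County05
20625,County05
20626,County06
20627,County06
20628,County06
20629,County06
20630,County06
20631,County07
20632,County07
20633,County07
20634,County07
20635,County07
20636,County08
20637,County08
20638,County08
20639,County08
20640,County08
20641,County09
20642,County09
20643,County09
20644,County09
20645,County09
20646,County10
20647,County10
20648,County10
20649,County10
20650,County10
20651,County11
20652,County11
20653,County11
20654,County11
20655,County11
20656,County12
20657,County12
20658,County12
20659,County12
20660,County12
20661,County13
20662,County13
20663,County13
20664,County13
20665,County13
20666,County14
20667,County14
20668,County14
20669,County14
20670,County14
20671,County15
20672,County15
20673,County15
20674,County15
20675,County15
20676,County16
20677,County16
20678,County16
20679,County16
20680,County16
20681,County17
20682,County17
20683,County17
20684,County17
20685,County17
20686,County18
20687,County18
20688,County18
20689,County18
20690,County18
20691,County19
20692,County19
20693,County19
20694,County19
20695,County19
20696,County20
20697,County20
20698,County20
20699,County20
20700,County20
20701,County21
20702,County21
20703,County21
20704,County21
20705,County21
20706,County22
20707,County22
20708,County22
20709,County22
20710,County22
20711,County23
20712,County23
20713,County23
20714,County23
20715,County23
20716,County24
20717,County24
20718,County24
20719,County24
20720,County24
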