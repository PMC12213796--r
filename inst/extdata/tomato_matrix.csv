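alternative,BI1,BI2,BI3,BI4,BI5,BI6,BI7
direction,benefit,benefit,cost,benefit,benefit,benefit,benefit
A1,72870.00,69588.63,3336.17,-7119.23,42065.15,13.64,9.43
A2,67450.00,61757.88,1963.68,-6664.80,40981.15,13.55,9.33
A3,58400.00,48917.63,3311.43,-6537.39,39171.15,12.70,9.18
A4,56800.00,47962.88,1999.19,-6318.86,38851.15,13.48,9.20
A5,37000.00,5022.63,3321.91,-3530.01,34891.15,12.22,9.73
A6,37600.00,8027.88,2013.90,-3888.43,35011.15,11.78,9.46
A7,40400.00,16517.63,3315.13,-4607.23,35571.15,12.17,9.32
A8,32200.00,3682.88,1975.35,-3970.31,33931.15,12.88,9.12
A9,44600.00,38249.43,3294.27,9929.74,38314.35,11.33,9.53
A10,37800.00,10823.57,2008.33,10977.96,36954.35,10.46,9.42
A11,48600.00,33713.32,3258.37,9118.41,39114.35,11.46,9.33
A12,43400.00,26278.57,1984.01,9638.28,38074.35,12.00,8.97
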