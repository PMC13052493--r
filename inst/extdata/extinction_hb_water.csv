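wavelength_nm,eps_hbo2_cm1_M1,eps_hb_cm1_M1,mua_water_mm1
650,368.0,3750.12,0.00032
660,319.6,3226.56,0.00036
670,294.0,2795.12,0.00041
680,277.6,2407.92,0.00045
690,276.0,2051.96,0.00050
700,290.0,1794.28,0.00060
710,314.0,1540.48,0.00075
720,348.0,1325.88,0.00115
730,390.0,1102.20,0.00180
740,446.0,1115.88,0.00260
750,518.0,1405.24,0.00265
760,586.0,1548.52,0.00270
770,650.0,1311.88,0.00255
780,710.0,1075.44,0.00235
790,756.0,890.80,0.00225
800,816.0,761.72,0.00220
810,864.0,717.08,0.00245
820,916.0,693.76,0.00275
830,974.0,693.44,0.00310
840,1022.0,692.36,0.00360
850,1058.0,691.32,0.00430
860,1092.0,691.16,0.00460
870,1114.0,689.50,0.00500
880,1154.0,726.44,0.00545
890,1176.0,743.60,0.00600
900,1198.0,761.84,0.00680
910,1220.0,780.20,0.00800
920,1234.0,797.28,0.01000
930,1238.0,809.24,0.01400
940,1214.0,804.28,0.02200
950,1190.0,793.52,0.03300
960,1186.0,781.16,0.04000
970,1154.0,772.44,0.04500
980,1134.0,772.44,0.04300
990,1100.0,768.48,0.04000
1000,1058.0,761.72,0.03600
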