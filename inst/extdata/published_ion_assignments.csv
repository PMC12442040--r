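table_no,cloud,series,mz_exp,intensity,best_match,composition_printed,ion,mz_the,delta_ppm_printed,neutral_formula,note
1,1,,851.7103,5.03e9,TG 50:3,C53 H96 O6 Na,[M+Na]+,851.7099,0.5,C53H96O6,
1,1,,853.7261,6.23e9,TG 50:2,C53 H98 O6 Na,[M+Na]+,853.7256,0.6,C53H98O6,
1,1,,867.6846,5.37e9,DG 53:9,C56 H92 O5 Na,[M+Na]+,867.6837,1.0,C56H92O5,
1,1,,869.7000,7.87e9,DG 53:8,C56 H94 O5 Na,[M+Na]+,869.6993,0.8,C56H94O5,
1,1,,871.7158,2.60e9,TG 50:1,C53 H100 O6 K,[M+K]+,871.7151,0.8,C53H100O6,
1,1,,879.7418,8.73e9,TG 52:3,C55 H100 O6 Na,[M+Na]+,879.7412,0.7,C55H100O6,
1,1,,881.7584,7.84e9,TG 52:2,C55 H102 O6 Na,[M+Na]+,881.7569,1.7,C55H102O6,
1,1,,893.6999,2.57e9,TG 52:4,C55 H98 O6 K,[M+K]+,893.6995,0.4,C55H98O6,
1,1,,895.7166,7.62e9,TG 52:3,C55 H100 O6 K,[M+K]+,895.7152,1.6,C55H100O6,printed theoretical sits at a 4-dp rounding boundary; composition-derived value is 895.71515 (rounds to 895.7151)
1,1,,897.7317,6.34e9,TG 52:2,C55 H102 O6 K,[M+K]+,897.7308,1.0,C55H102O6,
1,1,,907.7737,2.61e9,TG 54:3,C57 H104 O6 Na,[M+Na]+,907.7725,1.3,C57H104O6,
1,2,,549.4883,3.00e9,MG 30:0 or DG O-30:0,C33 H66 O4 Na,[M+Na]+,549.4853,5.5,C33H66O4,
1,2,,551.5038,1.52e9,MG 32:2 or DG O-32:2,C35 H67 O4,[M+H]+,551.5034,0.7,C35H66O4,
1,2,,573.4880,2.07e9,MG 32:2 or DG O-32:2,C35 H66 O4 Na,[M+Na]+,573.4853,4.7,C35H66O4,
1,2,,575.5039,1.53e9,MG 32:1 or DG O-32:1,C35 H68 O4 Na,[M+Na]+,575.5010,5.0,C35H68O4,
1,2,,577.5187,2.87e10,MG 32:0 or DG O-32:0,C35 H70 O4 Na,[M+Na]+,577.5166,3.6,C35H70O4,
1,2,,601.5189,7.51e9,MG 34:2 or DG O-34:2,C37 H70 O4 Na,[M+Na]+,601.5166,3.8,C37H70O4,
1,2,,603.5351,1.54e10,MG 34:1 or DG O-34:1,C37 H72 O4 Na,[M+Na]+,603.5323,4.6,C37H72O4,
1,2,,605.5510,3.53e9,MG 34:0 or DG O-34:0,C37 H74 O4 Na,[M+Na]+,605.5479,5.1,C37H74O4,
2,3,A1,820.5254,6.23e9,PC 36:4 or PE 39:4,C44 H80 N O8 P K,[M+K]+,820.5253,0.1,C44H80NO8P,
2,3,A1,822.5398,3.59e10,PC 36:3 or PE 39:3,C44 H82 N O8 P K,[M+K]+,822.5410,1.5,C44H82NO8P,
2,3,A1,824.5559,9.95e9,PC 36:2 or PE 39:2,C44 H84 N O8 P K,[M+K]+,824.5566,0.8,C44H84NO8P,
2,3,A1,826.5722,1.01e10,PC 36:1 or PE 39:1,C44 H86 N O8 P K,[M+K]+,826.5723,0.1,C44H86NO8P,
2,3,A2,796.5251,5.01e10,PC 34:2 or PE 37:2,C42 H80 N O8 P K,[M+K]+,796.5253,0.3,C42H80NO8P,
2,3,A2,798.5416,7.73e10,PC 34:1 or PE 37:1,C42 H82 N O8 P K,[M+K]+,798.5410,0.8,C42H82NO8P,
2,3,A2,806.5667,1.53e10,PC 36:3 or PE 39:3,C44 H82 N O8 P Na,[M+Na]+,806.5670,0.4,C44H82NO8P,
2,3,A2,808.5825,1.22e10,PC 36:2 or PE 39:2,C44 H84 N O8 P Na,[M+Na]+,808.5827,0.2,C44H84NO8P,
2,3,A3,763.4667,1.18e10,PA 38:4,C41 H73 O8 P K,[M+K]+,763.4675,1.0,C41H73O8P,
2,3,A3,765.4824,1.52e10,PA 38:3,C41 H75 O8 P K,[M+K]+,765.4831,0.9,C41H75O8P,
2,3,A3,770.5099,3.45e9,PC 32:1 or PE 35:1,C40 H78 N O8 P K,[M+K]+,770.5097,0.3,C40H78NO8P,
2,3,A3,780.5515,2.53e10,PC 34:2 or PE 37:2,C42 H80 N O8 P Na,[M+Na]+,780.5514,0.1,C42H80NO8P,
2,3,A3,782.5678,3.83e10,PC 34:1 or PE 37:1,C42 H82 N O8 P Na,[M+Na]+,782.5670,1.0,C42H82NO8P,
2,3,A3,786.6008,4.66e9,PC 36:2 or PE 39:2,C44 H84 N O8 P,[M+H]+,786.6007,0.1,C44H84NO8P,
2,3,A4,737.4516,1.98e10,PA 36:3,C39 H71 O8 P K,[M+K]+,737.4518,0.3,C39H71O8P,
2,3,A4,739.4676,3.21e10,PA 36:2,C39 H73 O8 P K,[M+K]+,739.4675,0.1,C39H73O8P,
2,3,A4,747.4930,9.13e9,PA 38:4,C41 H73 O8 P Na,[M+Na]+,747.4935,0.7,C41H73O8P,
2,3,A4,749.5087,5.76e9,PA 38:3,C41 H75 O8 P Na,[M+Na]+,749.5092,0.7,C41H75O8P,
2,3,A4,758.5695,7.66e9,PC 34:2 or PE 37:2,C42 H80 N O8 P,[M+H]+,758.5694,0.1,C42H80NO8P,
2,3,A4,760.5842,2.45e10,PC 34:1 or PE 37:1,C42 H82 N O8 P,[M+H]+,760.5851,1.2,C42H82NO8P,
2,3,A5,721.4773,8.68e9,PA 36:3,C39 H71 O8 P Na,[M+Na]+,721.4779,0.8,C39H71O8P,
2,3,A5,723.4932,1.98e10,PA 36:2,C39 H73 O8 P Na,[M+Na]+,723.4935,0.4,C39H73O8P,
2,3,A5,724.4974,1.42e9,PA 36:2 - first isotope,12C38 13C H73 O8 P Na,[M+Na]+,724.4970,0.6,C38 13C1 H73 O8 P,first-isotope row; printed theoretical is 1e-4 above the composition-derived value
2,3,A6,666.4834,3.28e8,?,?,-,,,,unidentified in source
2,3,A6,682.4575,1.46e8,?,?,-,,,,unidentified in source
2,3,A6,692.4991,5.40e8,?,?,-,,,,unidentified in source
2,3,B1,763.4667,1.18e10,PA 38:4,C41 H73 O8 P K,[M+K]+,763.4675,1.0,C41H73O8P,
2,3,B1,794.5095,7.04e9,PC 34:3 or PE 37:3,C42 H78 N O8 P K,[M+K]+,794.5097,0.3,C42H78NO8P,
2,3,B1,822.5398,3.59e10,PC 36:3 or PE 39:3,C44 H82 N O8 P K,[M+K]+,822.5410,1.5,C44H82NO8P,
2,3,B2,739.4676,3.73e10,PA 36:2,C39 H73 O8 P K,[M+K]+,739.4675,0.1,C39H73O8P,
2,3,B2,740.4702,1.06e10,PA 36:2 - first isotope,12C38 13C H73 O8 P K,[M+K]+,740.4709,0.9,C38 13C1 H73 O8 P,first-isotope row; printed theoretical is 1e-4 above the composition-derived value
2,3,B2,767.4999,3.02e9,PA 38:2,C41 H77 O8 P K,[M+K]+,767.4988,1.4,C41H77O8P,
2,3,B2,770.5099,3.45e9,PC 32:1 or PE 35:1,C40 H78 N O8 P K,[M+K]+,770.5097,0.3,C40H78NO8P,
2,3,B2,798.5405,7.73e10,PC 34:1 or PE 37:1,C42 H82 N O8 P K,[M+K]+,798.5410,0.6,C42H82NO8P,
2,3,B2,804.5505,7.73e10,PC 36:4 or PE 39:4,C44 H80 N O8 P Na,[M+Na]+,804.5514,1.1,C44H80NO8P,
2,3,B3,747.4930,9.13e9,PA 38:4,C41 H73 O8 P Na,[M+Na]+,747.4935,0.7,C41H73O8P,
2,3,B3,749.5087,5.75e9,PA 38:3,C41 H75 O8 P Na,[M+Na]+,749.5092,0.7,C41H75O8P,
2,3,B3,778.5357,1.76e10,PC 34:3 or PE 37:3,C42 H78 N O8 P Na,[M+Na]+,778.5357,0.0,C42H78NO8P,
2,3,B3,806.5668,1.53e10,PC 36:3 or PE 39:3,C44 H82 N O8 P Na,[M+Na]+,806.5670,0.2,C44H82NO8P,
2,3,B3,808.5823,8.95e9,PC 36:2 or PE 39:2,C44 H84 N O8 P Na,[M+Na]+,808.5827,0.5,C44H84NO8P,
2,3,B4,780.5515,2.53e10,PC 34:2 or PE 37:2,C42 H82 N O8 P Na,[M+Na]+,780.5514,0.1,C42H80NO8P,printed composition typo (one H2 high); corrected composition reproduces the printed theoretical m/z
2,3,B4,808.5825,1.22e10,PC 36:2 or PE 39:2,C44 H84 N O8 P Na,[M+Na]+,808.5827,0.2,C44H84NO8P,
2,3,B5,767.5464,5.83e8,SM 36:2;O2,C41 H81 N2 O6 P K,[M+K]+,767.5464,0.0,C41H81N2O6P,
2,3,B5,782.5663,3.83e10,PC 34:1 or PE 37:1,C42 H82 N O8 P Na,[M+Na]+,782.5670,0.9,C42H82NO8P,
2,3,B5,810.5988,1.77e9,PC 36:1 or PE 39:1,C44 H86 N O8 P Na,[M+Na]+,810.5983,0.6,C44H86NO8P,
2,3,B6,756.5548,1.77e8,PC 34:3 or PE 37:3,C42 H78 N O8 P,[M+H]+,756.5538,1.3,C42H78NO8P,
2,3,B6,784.5856,4.24e9,PC 36:3 or PE 39:3,C44 H82 N O8 P,[M+H]+,784.5851,0.6,C44H82NO8P,
2,3,B7,692.4991,5.40e8,?,?,-,,,,unidentified in source
2,3,B7,758.5696,7.66e9,PC 34:2 or PE 37:2,C42 H80 N O8 P,[M+H]+,758.5694,0.3,C42H80NO8P,
2,3,B7,786.6008,4.47e9,PC 36:2 or PE 39:2,C44 H84 N O8 P,[M+H]+,786.6007,0.1,C44H84NO8P,
2,3,B8,760.5842,2.45e10,PC 34:1 or PE 37:1,C42 H82 N O8 P,[M+H]+,760.5851,1.2,C42H82NO8P,
2,3,B8,774.6004,2.33e9,PC 35:1 or PE 38:1,C43 H84 N O8 P,[M+H]+,774.6007,0.4,C43H84NO8P,
2,3,B8,788.6159,7.59e8,PC 36:1 or PE 39:1,C44 H86 N O8 P,[M+H]+,788.6164,0.6,C44H86NO8P,
3,4,C1,476.3133,6.29e8,LPC O-14:0,C22 H48 N O6 P Na,[M+Na]+,476.3111,4.6,C22H48NO6P,
3,4,C1,478.3289,1.81e10,LPE O-19:2,C24 H48 N O6 P,[M+H]+,478.3292,0.6,C24H48NO6P,
3,4,C1,500.3135,6.19e7,LPE O-21:2,C26 H52 N O6 P,[M+Na]+,500.3111,4.8,C24H48NO6P,printed composition inconsistent with printed theoretical m/z; value corresponds to sodiated LPE O-19:2
3,4,C1,502.3289,2.93e10,LPC O-16:1,C24 H50 N O6 P Na,[M+Na]+,502.3268,4.2,C24H50NO6P,
3,4,C1,504.3444,8.60e10,LPC O-16:0,C24 H52 N O6 P Na,[M+Na]+,504.3424,4.0,C24H52NO6P,
3,4,C1,506.3604,4.11e9,LPC O-18:2,C26 H52 N O6 P,[M+H]+,506.3605,0.2,C26H52NO6P,
3,4,C2,441.2978,5.40e8,ST 26:2;O4,C26 H42 O4 Na,[M+Na]+,441.2975,0.7,C26H42O4,
3,4,C2,469.3293,7.68e8,ST 28:2;O4,C28 H46 O4 Na,[M+Na]+,469.3288,1.1,C28H46O4,
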