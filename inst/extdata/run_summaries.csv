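strain,lignin_gL,C_BM_min,C_BM_max,C_Glc_min,C_Glc_max,C_Xyl_min,C_Xyl_max,C_Ara_min,C_Ara_max,C_LA_max,FT_h,purity_L_pct,P_reported,Y_BM_Sub_reported,Y_LA_Sub_reported,Y_LA_BM_reported
DSM_2314,0.000,0.03,6.09,0.00,46.21,0.00,21.81,0.00,10.44,68.85,26,98.89,2.648,0.0776,0.8775,11.305
DSM_2314,0.625,0.04,7.78,0.00,44.64,0.00,22.36,0.00,10.76,63.71,72,98.89,0.885,0.1000,0.8192,8.189
DSM_ID_14_298,0.000,0.02,4.33,0.00,46.69,0.00,21.33,0.00,10.58,69.68,28,99.51,2.488,0.0612,0.5746,9.391
DSM_ID_14_298,0.625,0.04,5.92,0.00,45.57,0.00,20.68,0.00,10.66,67.07,48,99.70,1.397,0.0682,0.6329,9.275
DSM_ID_14_298,1.250,0.07,5.29,0.00,44.58,0.00,22.75,0.00,10.95,66.00,48,99.64,1.375,0.0686,0.6045,8.813
DSM_ID_14_301,0.000,0.03,5.00,11.90,49.78,11.27,21.22,8.81,11.70,46.95,48,99.63,0.978,0.0708,0.5837,8.239
DSM_ID_14_301,0.625,0.08,4.81,7.38,47.39,7.09,21.84,7.63,10.77,50.64,48,98.93,1.055,0.0555,0.8591,11.771
DSM_ID_14_301,1.250,0.07,5.17,0.00,42.76,11.55,22.02,8.77,10.58,45.56,48,98.89,0.949,0.0764,0.8993,15.490
DSM_ID_14_301,2.500,0.06,5.31,0.00,41.82,11.16,22.43,7.07,10.55,43.75,48,98.94,0.912,0.0676,0.8432,12.475
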