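metric,modality,stratum,median,q1,q3
SUL_max,db,le2.5,12.39,10.23,14.6
SUL_max,db,gt2.5,14.22,9.46,17.92
SUL_max,wb,le2.5,7.52,5.17,8.78
SUL_max,wb,gt2.5,8.04,5.23,11.38
SUL_mean,db,le2.5,5.78,4.37,7.01
SUL_mean,db,gt2.5,4.00,3.45,5.32
SUL_mean,wb,le2.5,3.56,2.65,4.08
SUL_mean,wb,gt2.5,3.35,2.87,4.18
SUL_peak,db,le2.5,11.05,8.15,12.22
SUL_peak,db,gt2.5,7.11,5.38,10.05
SUL_peak,wb,le2.5,4.07,3.07,4.29
SUL_peak,wb,gt2.5,4.50,3.51,6.81
TBR_liver,wb,le2.5,2.39,1.87,2.64
TBR_liver,wb,gt2.5,2.71,2.07,3.92
TBR_contralateral,db,le2.5,4.01,3.65,7.17
TBR_contralateral,db,gt2.5,13.41,8.97,18.78
TBR_contralateral,wb,le2.5,16.64,7.09,24.44
TBR_contralateral,wb,gt2.5,14.22,5.20,20.45
MTV_mL,db,le2.5,9.00,5.39,12.02
MTV_mL,db,gt2.5,17.25,10.39,44.53
MTV_mL,wb,le2.5,5.8,4.26,7.26
MTV_mL,wb,gt2.5,24.85,16.49,79.56
TLG,db,le2.5,54.84,24.51,84.43
TLG,db,gt2.5,83.57,47.66,145.2
TLG,wb,le2.5,25.06,16.19,30.34
TLG,wb,gt2.5,64.53,62.24,95.4
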