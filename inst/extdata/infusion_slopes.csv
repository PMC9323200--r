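region,group,trial_id,slope_ul_per_ul
cortical,nhp,C1-a,2.86
cortical,nhp,C1-b,3.90
cortical,nhp,C1-c,3.07
cortical,nhp,C1-d,4.61
cortical,nhp,C2-a,2.67
cortical,nhp,C2-b,3.05
cortical,nhp,CT-a,3.07
cortical,agar,gel-1,3.03
cortical,agar,gel-2,2.69
cortical,agar,gel-3,2.72
cortical,agar,gel-4,4.74
cortical,agar,gel-5,4.11
cortical,agar,gel-6,4.67
cortical,agar,gel-7,4.23
cortical,agar,gel-8,3.10
cortical,agar,gel-9,4.81
cortical,agar,gel-10,3.82
thalamic,nhp,T1-a,3.48
thalamic,nhp,T2-a,3.59
thalamic,nhp,T2-b,3.30
thalamic,nhp,CT-b,6.38
thalamic,agar,gel-1,2.63
thalamic,agar,gel-2,3.71
thalamic,agar,gel-3,4.02
thalamic,agar,gel-4,2.66
thalamic,agar,gel-5,3.17
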