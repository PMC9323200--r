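trial_id,group,region,time_min,infused_uL,measured_uL
MTL1-left,nhp,mtl,NA,15,221.1
MTL1-right,nhp,mtl,NA,15,212.2
MTL2-left,nhp,mtl,NA,20,285.3
MTL3-right,nhp,mtl,NA,20,204.7
gel-1,agar,mtl,36,15,196.7
gel-2,agar,mtl,36,15,229.2
gel-3,agar,mtl,36,15,260.2
gel-4,agar,mtl,36,15,220.7
gel-5,agar,mtl,36,15,207.0
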