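feature_id,feature_name,disease,category,source,tp,fp,fn,tn,prevalence,sens,spec,N
EX001,worked example test,example condition,Lab/Diagnostic Tests,synthetic_example,160,80,40,720,,,,
EX002,bedside ultrasound (synthetic),example condition A,Imaging,synthetic_example,,,,,0.30,1.0,1.0,200
EX003,focal sign (synthetic),example condition B,Signs/Symptoms/History,synthetic_example,,,,,0.20,0.65,0.90,850
EX004,male sex (synthetic),example condition C,Demographics,synthetic_example,,,,,0.15,0.55,0.50,1200
EX005,serum marker (synthetic),example condition D,Lab/Diagnostic Tests,synthetic_example,,,,,0.40,0.85,0.75,320
EX006,radiograph finding (synthetic),example condition E,Imaging,synthetic_example,,,,,0.25,0.70,0.95,540
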