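pt,soc
Rash,Skin and subcutaneous tissue disorders
Drug eruption,Skin and subcutaneous tissue disorders
Erythema,Skin and subcutaneous tissue disorders
Vitiligo,Skin and subcutaneous tissue disorders
Alopecia areata,Skin and subcutaneous tissue disorders
Pyrexia,General disorders and administration site conditions
Infusion-related reaction,"Injury, poisoning and procedural complications"
Cytomegalovirus infection,Infections and infestations
Autoimmune hepatitis,Hepatobiliary disorders
Myocarditis,Cardiac disorders
Glomerulonephritis,Renal and urinary disorders
Nephrotic syndrome,Renal and urinary disorders
Myasthenia gravis,Nervous system disorders
Autoimmune thyroiditis,Endocrine disorders
Myositis,Musculoskeletal and connective tissue disorders
Neutropenia,Blood and lymphatic system disorders
Thrombocytopenia,Blood and lymphatic system disorders
Pemphigoid,Skin and subcutaneous tissue disorders
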