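# ICD-10-CM chapters; 3-character prefix ranges compared lexicographically
# (alphanumeric third characters such as O9A sort after O99's digits,
# which the lo/hi bounds account for).
- {label: "Certain infectious and parasitic diseases (A00-B99)", kind: range, lo: "A00", hi: "B99", prefix_len: 3}
- {label: "Neoplasms (C00-D49)", kind: range, lo: "C00", hi: "D49", prefix_len: 3}
- {label: "Diseases of the blood and blood-forming organs (D50-D89)", kind: range, lo: "D50", hi: "D8Z", prefix_len: 3}
- {label: "Endocrine, nutritional and metabolic diseases (E00-E89)", kind: range, lo: "E00", hi: "E8Z", prefix_len: 3}
- {label: "Mental, behavioral and neurodevelopmental disorders (F01-F99)", kind: range, lo: "F01", hi: "F99", prefix_len: 3}
- {label: "Diseases of the nervous system (G00-G99)", kind: range, lo: "G00", hi: "G99", prefix_len: 3}
- {label: "Diseases of the eye and adnexa (H00-H59)", kind: range, lo: "H00", hi: "H5Z", prefix_len: 3}
- {label: "Diseases of the ear and mastoid process (H60-H95)", kind: range, lo: "H60", hi: "H9Z", prefix_len: 3}
- {label: "Diseases of the circulatory system (I00-I99)", kind: range, lo: "I00", hi: "I99", prefix_len: 3}
- {label: "Diseases of the respiratory system (J00-J99)", kind: range, lo: "J00", hi: "J99", prefix_len: 3}
- {label: "Diseases of the digestive system (K00-K95)", kind: range, lo: "K00", hi: "K9Z", prefix_len: 3}
- {label: "Diseases of the skin and subcutaneous tissue (L00-L99)", kind: range, lo: "L00", hi: "L99", prefix_len: 3}
- {label: "Diseases of the musculoskeletal system and connective tissue (M00-M99)", kind: range, lo: "M00", hi: "M99", prefix_len: 3}
- {label: "Diseases of the genitourinary system (N00-N99)", kind: range, lo: "N00", hi: "N99", prefix_len: 3}
- {label: "Pregnancy, childbirth and the puerperium (O00-O9A)", kind: range, lo: "O00", hi: "O9Z", prefix_len: 3}
- {label: "Certain conditions originating in the perinatal period (P00-P96)", kind: range, lo: "P00", hi: "P9Z", prefix_len: 3}
- {label: "Congenital malformations, deformations and chromosomal abnormalities (Q00-Q99)", kind: range, lo: "Q00", hi: "Q99", prefix_len: 3}
- {label: "Symptoms, signs and abnormal clinical and laboratory findings (R00-R99)", kind: range, lo: "R00", hi: "R99", prefix_len: 3}
- {label: "Injury, poisoning and certain other consequences of external causes (S00-T88)", kind: range, lo: "S00", hi: "T8Z", prefix_len: 3}
- {label: "External causes of morbidity (V00-Y99)", kind: range, lo: "V00", hi: "Y99", prefix_len: 3}
- {label: "Factors influencing health status and contact with health services (Z00-Z99)", kind: range, lo: "Z00", hi: "Z99", prefix_len: 3}
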