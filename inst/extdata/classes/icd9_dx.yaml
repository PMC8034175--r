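# ICD-9-CM diagnosis chapters; E/V supplementary classifications first so
# the numeric ranges only see purely numeric prefixes.
- {label: "Supplementary Classification Of External Causes Of Injury And Poisoning (E000-E999)", kind: first_char, chars: [E]}
- {label: "Supplementary Classification Of Factors Influencing Health Status (V01-V91)", kind: first_char, chars: [V]}
- {label: "Infectious And Parasitic Diseases (001-139)", kind: range, lo: "001", hi: "139", prefix_len: 3}
- {label: "Neoplasms (140-239)", kind: range, lo: "140", hi: "239", prefix_len: 3}
- {label: "Endocrine, Nutritional And Metabolic Diseases, And Immunity Disorders (240-279)", kind: range, lo: "240", hi: "279", prefix_len: 3}
- {label: "Diseases Of The Blood And Blood-Forming Organs (280-289)", kind: range, lo: "280", hi: "289", prefix_len: 3}
- {label: "Mental Disorders (290-319)", kind: range, lo: "290", hi: "319", prefix_len: 3}
- {label: "Diseases Of The Nervous System And Sense Organs (320-389)", kind: range, lo: "320", hi: "389", prefix_len: 3}
- {label: "Diseases Of The Circulatory System (390-459)", kind: range, lo: "390", hi: "459", prefix_len: 3}
- {label: "Diseases Of The Respiratory System (460-519)", kind: range, lo: "460", hi: "519", prefix_len: 3}
- {label: "Diseases Of The Digestive System (520-579)", kind: range, lo: "520", hi: "579", prefix_len: 3}
- {label: "Diseases Of The Genitourinary System (580-629)", kind: range, lo: "580", hi: "629", prefix_len: 3}
- {label: "Complications Of Pregnancy, Childbirth, And The Puerperium (630-679)", kind: range, lo: "630", hi: "679", prefix_len: 3}
- {label: "Diseases Of The Skin And Subcutaneous Tissue (680-709)", kind: range, lo: "680", hi: "709", prefix_len: 3}
- {label: "Diseases Of The Musculoskeletal System And Connective Tissue (710-739)", kind: range, lo: "710", hi: "739", prefix_len: 3}
- {label: "Congenital Anomalies (740-759)", kind: range, lo: "740", hi: "759", prefix_len: 3}
- {label: "Certain Conditions Originating In The Perinatal Period (760-779)", kind: range, lo: "760", hi: "779", prefix_len: 3}
- {label: "Symptoms, Signs, And Ill-Defined Conditions (780-799)", kind: range, lo: "780", hi: "799", prefix_len: 3}
- {label: "Injury And Poisoning (800-999)", kind: range, lo: "800", hi: "999", prefix_len: 3}
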