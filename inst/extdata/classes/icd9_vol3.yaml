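# ICD-9-CM Volume 3 procedure chapters; rules compare the 2-character code
# prefix lexicographically (codes are stored without decimal points).
- {label: "Procedures And Interventions, Not Elsewhere Classified (00)", kind: range, lo: "00", hi: "00", prefix_len: 2}
- {label: "Operations on the Nervous System (01-05)", kind: range, lo: "01", hi: "05", prefix_len: 2}
- {label: "Operations on the Endocrine System (06-07)", kind: range, lo: "06", hi: "07", prefix_len: 2}
- {label: "Operations on the Eye (08-16)", kind: range, lo: "08", hi: "16", prefix_len: 2}
- {label: "Other Miscellaneous Diagnostic and Therapeutic Procedures (17)", kind: range, lo: "17", hi: "17", prefix_len: 2}
- {label: "Operations on the Ear (18-20)", kind: range, lo: "18", hi: "20", prefix_len: 2}
- {label: "Operations on the Nose, Mouth, and Pharynx (21-29)", kind: range, lo: "21", hi: "29", prefix_len: 2}
- {label: "Operations on the Respiratory System (30-34)", kind: range, lo: "30", hi: "34", prefix_len: 2}
- {label: "Operations on the Cardiovascular System (35-39)", kind: range, lo: "35", hi: "39", prefix_len: 2}
- {label: "Operations on the Hemic and Lymphatic System (40-41)", kind: range, lo: "40", hi: "41", prefix_len: 2}
- {label: "Operations on the Digestive System (42-54)", kind: range, lo: "42", hi: "54", prefix_len: 2}
- {label: "Operations on the Urinary System (55-59)", kind: range, lo: "55", hi: "59", prefix_len: 2}
- {label: "Operations on the Male Genital Organs (60-64)", kind: range, lo: "60", hi: "64", prefix_len: 2}
- {label: "Operations on the Female Genital Organs (65-71)", kind: range, lo: "65", hi: "71", prefix_len: 2}
- {label: "Obstetrical Procedures (72-75)", kind: range, lo: "72", hi: "75", prefix_len: 2}
- {label: "Operations on the Musculoskeletal System (76-84)", kind: range, lo: "76", hi: "84", prefix_len: 2}
- {label: "Operations on the Integumentary System (85-86)", kind: range, lo: "85", hi: "86", prefix_len: 2}
- {label: "Miscellaneous Diagnostic and Therapeutic Procedures (87-99)", kind: range, lo: "87", hi: "99", prefix_len: 2}
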