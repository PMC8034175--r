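# ICD-10-PCS sections, identified by the first code character.
- {label: "Medical and Surgical (0)", kind: first_char, chars: ["0"]}
- {label: "Obstetrics (1)", kind: first_char, chars: ["1"]}
- {label: "Placement (2)", kind: first_char, chars: ["2"]}
- {label: "Administration (3)", kind: first_char, chars: ["3"]}
- {label: "Measurement and Monitoring (4)", kind: first_char, chars: ["4"]}
- {label: "Extracorporeal or Systemic Assistance and Performance (5)", kind: first_char, chars: ["5"]}
- {label: "Extracorporeal or Systemic Therapies (6)", kind: first_char, chars: ["6"]}
- {label: "Osteopathic (7)", kind: first_char, chars: ["7"]}
- {label: "Other Procedures (8)", kind: first_char, chars: ["8"]}
- {label: "Chiropractic (9)", kind: first_char, chars: ["9"]}
- {label: "Imaging (B)", kind: first_char, chars: [B]}
- {label: "Nuclear Medicine (C)", kind: first_char, chars: [C]}
- {label: "Radiation Therapy (D)", kind: first_char, chars: [D]}
- {label: "Physical Rehabilitation and Diagnostic Audiology (F)", kind: first_char, chars: [F]}
- {label: "Mental Health (G)", kind: first_char, chars: [G]}
- {label: "Substance Abuse Treatment (H)", kind: first_char, chars: [H]}
- {label: "New Technology (X)", kind: first_char, chars: [X]}
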