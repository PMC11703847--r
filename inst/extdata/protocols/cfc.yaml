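# Contextual fear conditioning: acquisition in A, extinction in B,
# then renewal (group 1, back to A) vs repeated extinction (group 2).
name: cfc
groups:
  "1":
    - {label: CFC1, count: 5,  expression: "AX+", gap_minutes_after: 1440}
    - {label: CFC2, count: 15, expression: "BX-", gap_minutes_after: 1440}
    - {label: CFC3, count: 3,  expression: "AX-"}
  "2":
    - {label: CFC1, count: 5,  expression: "AX+", gap_minutes_after: 1440}
    - {label: CFC2, count: 15, expression: "BX-", gap_minutes_after: 1440}
    - {label: CFC3, count: 3,  expression: "BX-"}
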