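# Fear response at different shock magnitudes during acquisition:
# 2 / 10 / 20 / 30 shock-paired episodes, then 15 extinction cycles.
name: shock_magnitude
groups:
  "1":
    - {label: SM1, count: 2,  expression: "AX+", gap_minutes_after: 1440}
    - {label: SM2, count: 15, expression: "BX-"}
  "2":
    - {label: SM1, count: 10, expression: "AX+", gap_minutes_after: 1440}
    - {label: SM2, count: 15, expression: "BX-"}
  "3":
    - {label: SM1, count: 20, expression: "AX+", gap_minutes_after: 1440}
    - {label: SM2, count: 15, expression: "BX-"}
  "4":
    - {label: SM1, count: 30, expression: "AX+", gap_minutes_after: 1440}
    - {label: SM2, count: 15, expression: "BX-"}
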