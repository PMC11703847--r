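# Shock-stress ordering: whether a single shock in B before (groups 3-4)
# or repeated shocks in A (groups 2, 4) change fear tested in B then A.
name: shock_stress
groups:
  "1":
    - {label: SS1, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SS2, count: 15, expression: "A",  gap_minutes_after: 1440}
    - {label: SS3, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SS4, count: 1,  expression: "A"}
  "2":
    - {label: SS1, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SS2, count: 15, expression: "A+", gap_minutes_after: 1440}
    - {label: SS3, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SS4, count: 1,  expression: "A"}
  "3":
    - {label: SS1, count: 1,  expression: "B+", gap_minutes_after: 1440}
    - {label: SS2, count: 15, expression: "A",  gap_minutes_after: 1440}
    - {label: SS3, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SS4, count: 1,  expression: "A"}
  "4":
    - {label: SS1, count: 1,  expression: "B+", gap_minutes_after: 1440}
    - {label: SS2, count: 15, expression: "A+", gap_minutes_after: 1440}
    - {label: SS3, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SS4, count: 1,  expression: "A"}
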