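# Stress-enhanced fear learning: multi-shock trauma in context A
# amplifies single-shock learning in context B.
name: sefl
groups:
  "1":
    - {label: SEFL1, count: 15, expression: "A",  gap_minutes_after: 1440}
    - {label: SEFL2, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SEFL3, count: 1,  expression: "B"}
  "2":
    - {label: SEFL1, count: 15, expression: "A",  gap_minutes_after: 1440}
    - {label: SEFL2, count: 1,  expression: "B+", gap_minutes_after: 1440}
    - {label: SEFL3, count: 1,  expression: "B"}
  "3":
    - {label: SEFL1, count: 15, expression: "A+", gap_minutes_after: 1440}
    - {label: SEFL2, count: 1,  expression: "B",  gap_minutes_after: 1440}
    - {label: SEFL3, count: 1,  expression: "B"}
  "4":
    - {label: SEFL1, count: 15, expression: "A+", gap_minutes_after: 1440}
    - {label: SEFL2, count: 1,  expression: "B+", gap_minutes_after: 1440}
    - {label: SEFL3, count: 1,  expression: "B"}
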