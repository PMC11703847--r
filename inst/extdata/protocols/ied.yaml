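# Immediate extinction deficit: extinction (or context exposure) either
# 15 minutes or 24 hours after acquisition; retention tested in C at 48 h.
# Gaps are chosen so that phase starts land at 15 min / 24 h / 48 h after
# the end of acquisition, with one episode advancing the clock by 1 min.
name: ied
groups:
  "1":
    - {label: IED1, count: 5, expression: "AX+",  gap_minutes_after: 15}
    - {label: IED2, count: 5, expression: "BX-",  gap_minutes_after: 1420}
    - {label: HOME, count: 1, expression: "Home", gap_minutes_after: 1440}
    - {label: IED3, count: 3, expression: "CX-"}
  "2":
    - {label: IED1, count: 5, expression: "AX+",  gap_minutes_after: 30}
    - {label: HOME, count: 1, expression: "Home", gap_minutes_after: 1404}
    - {label: IED2, count: 5, expression: "BX-",  gap_minutes_after: 1435}
    - {label: IED3, count: 3, expression: "CX-"}
  "3":
    - {label: IED1, count: 5, expression: "AX+",  gap_minutes_after: 15}
    - {label: IED2, count: 5, expression: "B",    gap_minutes_after: 1420}
    - {label: HOME, count: 1, expression: "Home", gap_minutes_after: 1440}
    - {label: IED3, count: 3, expression: "CX-"}
  "4":
    - {label: IED1, count: 5, expression: "AX+",  gap_minutes_after: 30}
    - {label: HOME, count: 1, expression: "Home", gap_minutes_after: 1404}
    - {label: IED2, count: 5, expression: "B",    gap_minutes_after: 1435}
    - {label: IED3, count: 3, expression: "CX-"}
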