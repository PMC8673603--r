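{
  "1": "BPI",
  "2": "BPI",
  "3": "BPI",
  "4": "BPI",
  "5": "LPI",
  "6": "LPI",
  "7": "LPI",
  "8": "LPI",
  "9": "PII",
  "10": "PII",
  "11": "PII",
  "12": "PII",
  "13": "PII",
  "tc_protoconid": "TIP_CRUSH",
  "tc_metaconid": "TIP_CRUSH",
  "tc_hypoconid": "TIP_CRUSH",
  "tc_entoconid": "TIP_CRUSH"
}
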