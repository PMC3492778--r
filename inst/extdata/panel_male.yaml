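panel:
  - name: "(Z)-9-C23:1"
    class: unsaturated
  - name: "(Z)-7-C23:1"
    class: unsaturated
  - name: "(Z)-5-C23:1"
    class: unsaturated
  - name: "C23"
    class: linear
  - name: "2-Me-C24"
    class: methylated
  - name: "(Z)-9-C25:1"
    class: unsaturated
  - name: "(Z)-7-C25:1"
    class: unsaturated
  - name: "(Z)-5-C25:1"
    class: unsaturated
  - name: "C25"
    class: linear
  - name: "2-Me-C26"
    class: methylated
  - name: "C27"
    class: linear
  - name: "2-Me-C28"
    class: methylated
  - name: "C29"
    class: linear
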