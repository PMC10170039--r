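# Model B — three divisions mirroring the three dimensions under study:
# efficiency (resource use), quality and access.  Patient volumes flow as
# links from the efficiency division to the quality (E7 inpatients, E9
# surgeries) and access (E8 outpatient visits) divisions.  Documented
# reconstruction; override with a user file if needed.
name: B
divisions: [efficiency, quality, access]
inputs:
  efficiency: [E1, E2, E3, E4]
desirable_outputs:
  quality: [Q1, Q2, Q3]
  access: [A1]
undesirable_outputs:
  quality: [Q4, Q5, Q6, Q7]
  access: [A2, A3]
links:
  - [efficiency, quality, E7]
  - [efficiency, quality, E9]
  - [efficiency, access, E8]
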