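# Model C — same structure as model A but with the financial labour
# variables: personnel costs (E5) replace staff hours (E2, E3) and
# outsourcing costs (E6) join the operations inputs.
name: C
divisions: [operations, inpatient, outpatient, surgical]
inputs:
  operations: [E1, E4, E5, E6]
desirable_outputs:
  inpatient: [Q1, Q2]
  outpatient: [Q3]
  surgical: [A1]
undesirable_outputs:
  inpatient: [Q4, Q5]
  outpatient: [A2]
  surgical: [Q6, Q7, A3]
links:
  - [operations, inpatient, E7]
  - [operations, outpatient, E8]
  - [operations, surgical, E9]
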