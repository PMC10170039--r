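# Model A — four divisions: hospital operations plus the three clinical
# services.  Operations consumes capacity, labour and operating costs and
# delivers the patient volumes (E7 inpatients, E8 outpatient visits, E9
# surgeries) as links to the service divisions, which emit the quality and
# access outcomes.  This wiring is a documented reconstruction of the usual
# hospital production layout; override with a user file if needed.
name: A
divisions: [operations, inpatient, outpatient, surgical]
inputs:
  operations: [E1, E2, E3, E4]
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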