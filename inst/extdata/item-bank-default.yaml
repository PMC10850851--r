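version: default-1.0
items:
- id: 1
  text: 'Orientation: what year is it?'
  block: inquiry
  feature: F3
  page: 1
  reminder: 'Correct response: the current year'
- id: 2
  text: 'Orientation: what day of the week is it?'
  block: inquiry
  feature: F3
  page: 1
  reminder: 'Correct response: the current day of the week'
- id: 3
  text: 'Orientation: what type of place is this?'
  block: inquiry
  feature: F3
  page: 1
- id: 4
  text: 'Attention: repeat the digits 7-5-1 backward'
  block: inquiry
  feature: F2
  page: 2
- id: 5
  text: 'Attention: repeat the digits 8-2-4-3 backward'
  block: inquiry
  feature: F2
  page: 2
  reminder: 'Correct response: 3-4-2-8'
- id: 6
  text: 'Attention: name the days of the week backward'
  block: inquiry
  feature: F2
  page: 3
- id: 7
  text: 'Attention: name the months of the year backward'
  block: inquiry
  feature: F2
  page: 3
- id: 8
  text: 'Symptom probe: have you felt confused during the past day?'
  block: inquiry
  feature: F1
  page: 4
- id: 9
  text: 'Symptom probe: did you think you were not in the hospital?'
  block: inquiry
  feature: F1
  page: 4
- id: 10
  text: 'Symptom probe: did you see things that were not really there?'
  block: inquiry
  feature: F1
  page: 4
- id: 11
  text: 'Observation: patient is sleepy or stuporous during assessment'
  block: observation
  feature: F4
  page: 5
  cue: Rate positive if the patient dozes off or is hard to arouse
- id: 12
  text: 'Observation: patient is hypervigilant'
  block: observation
  feature: F4
  page: 5
  cue: Rate positive for an inappropriately heightened startle/alertness
- id: 13
  text: 'Observation: level of consciousness is other than alert'
  block: observation
  feature: F4
  page: 5
  cue: Any state other than calm wakefulness counts as positive
- id: 14
  text: 'Observation: flow of ideas is unclear or illogical'
  block: observation
  feature: F3
  page: 6
  cue: Rambling, irrelevant or incoherent answers are positive
- id: 15
  text: 'Observation: conversation is rambling or off-target'
  block: observation
  feature: F3
  page: 6
  cue: Positive when the patient cannot keep to the question asked
- id: 16
  text: 'Observation: speech is unusually sparse or sparse-then-pressured'
  block: observation
  feature: F3
  page: 6
  cue: Marked poverty or pressure of speech is positive
- id: 17
  text: 'Observation: answers are internally inconsistent'
  block: observation
  feature: F3
  page: 6
  cue: Self-contradictory statements within the interview are positive
- id: 18
  text: 'Observation: patient has trouble keeping track of the questions'
  block: observation
  feature: F2
  page: 7
  cue: Needing repeated re-orienting to the task is positive
- id: 19
  text: 'Observation: patient is easily distracted by surroundings'
  block: observation
  feature: F2
  page: 7
  cue: Attention captured by irrelevant stimuli is positive
- id: 20
  text: 'Observation: patient''s attention waxes and wanes'
  block: observation
  feature: F2
  page: 7
  cue: Fluctuating engagement with the interview is positive
- id: 21
  text: 'Selective: evidence of fluctuation during this assessment'
  block: selective
  feature: F1
  page: 8
- id: 22
  text: 'Selective: acute change from the patient''s baseline record'
  block: selective
  feature: F1
  auto_derived: yes
pages:
- - 1
  - 2
  - 3
- - 4
  - 5
- - 6
  - 7
- - 8
  - 9
  - 10
- - 11
  - 12
  - 13
- - 14
  - 15
  - 16
  - 17
- - 18
  - 19
  - 20
- 21
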