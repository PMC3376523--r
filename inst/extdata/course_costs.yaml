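# Itemized per-class-fixed and per-participant-variable delivery costs (AUD),
# class capacity 20 for both modes.
face_to_face:
  class_capacity: 20
  facilitator_hours: 9
  facilitator_rate: 90
  items:
    - {name: venue, amount: 1000, recurrence: per-class-fixed, payer: provider}
    - {name: presentation equipment rental, amount: 500, recurrence: per-class-fixed, payer: provider}
    - {name: facilitator remuneration, amount: 810, recurrence: per-class-fixed, payer: provider}
    - {name: faculty ICT support fee, amount: 500, recurrence: per-class-fixed, payer: provider}
    - {name: administrative support, amount: 250, recurrence: per-class-fixed, payer: provider}
    - {name: catering, amount: 25, recurrence: per-participant-variable, payer: provider}
    - {name: stationery consumables, amount: 5, recurrence: per-participant-variable, payer: provider}
    - {name: delivery support DVD, amount: 5, recurrence: per-participant-variable, payer: provider}
web:
  class_capacity: 20
  facilitator_hours: 14
  facilitator_rate: 60
  items:
    - {name: facilitator remuneration, amount: 840, recurrence: per-class-fixed, payer: provider}
    - {name: faculty ICT support fee, amount: 500, recurrence: per-class-fixed, payer: provider}
    - {name: administrative support, amount: 250, recurrence: per-class-fixed, payer: provider}
    - {name: stationery consumables, amount: 3, recurrence: per-participant-variable, payer: provider}
    - {name: delivery support DVD, amount: 5, recurrence: per-participant-variable, payer: provider}
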