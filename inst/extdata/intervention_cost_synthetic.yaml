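# Synthetic illustrative micro-costing inputs for a sessional modular
# psychological intervention (not published national figures). At these
# values the per-session cost works out to GBP 80.41.
therapist_cost_per_hour: 40.0        # delivery band, GBP per working hour
supervisor_cost_per_hour: 55.0       # senior supervising bands, GBP per hour
face_to_face_hours_per_session: 1.0
indirect_to_face_ratio: 0.75         # indirect hours per face-to-face hour
supervision_hours_per_participant: 2.5
training_cost_total: 8677.53         # GBP, amortised over the cohort below
training_amortisation_n: 166
sessions_reference: 18.23            # sessions per participant for shares
scaling_factor: 1.0                  # 1 = fully additional to usual care
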