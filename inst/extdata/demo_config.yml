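seed: 7
simulate: true
n_participants: 14
daily_rate: 60
zero_policy: strict
alpha: 0.0001
windows:
  before: ["2020-01-01", "2020-03-01"]
  excluded: ["2020-03-01", "2020-03-29"]
  after: ["2020-03-29", "2020-06-01"]
  tz: "America/New_York"
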