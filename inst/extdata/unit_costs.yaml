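# Societal-perspective unit costs (synthetic defaults, euro)
unit_costs:
  consultation: 100
  hospital_admission: 4000
hourly_rate: 35
bt_platform_cost: 300
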