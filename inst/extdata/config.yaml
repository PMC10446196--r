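delimiter: ","
eligible_counties: [County02, County03, County07, County08, County10, County15, County19, County23]
reference:
  zip_county_map: zip_county_map.csv
  channel_calendar: channel_calendar.csv
  speedbump_key: speedbump_key.csv
simulate:
  n_total: 50
  mix: {legitimate: 0.7, professional: 0.1, bot: 0.2}
  seed: 7
  n_counties: 24
  n_eligible: 8
  map_seed: 7
logging:
  level: warn
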