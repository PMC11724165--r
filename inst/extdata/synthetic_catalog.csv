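event_id,year,magnitude,rupture_length_km
DEMO0001,2021,7.4,
DEMO0002,2022,6.9,
DEMO0003,2001,8.1,426
DEMO0004,1997,7.5,170
DEMO0005,1951,8.0,
DEMO0006,1920,7.0,
DEMO0007,1654,8.0,
DEMO0008,-325,7.0,
DEMO0009,2010,6.8,
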