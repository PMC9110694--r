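Name: synthetic-estriol-16-glucuronide
PrecursorMZ: 463.196800
RETENTIONTIME: 118.40
Num Peaks: 4
85.029500 12.00
113.024400 35.00
271.169800 100.00
287.164700 22.00

Name: synthetic-estrone-3-sulfate
PrecursorMZ: 349.111500
RETENTIONTIME: 201.10
Num Peaks: 3
96.960100 100.00
145.064800 18.00
269.154200 41.00

Name: synthetic-pregnanediol-3-glucuronide
PrecursorMZ: 495.295700
RETENTIONTIME: 243.80
Num Peaks: 4
75.008800 9.00
113.024400 55.00
319.263300 100.00
337.273900 30.00
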