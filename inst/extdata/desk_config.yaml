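# Desk-scale run of the sodium-MRI QA pipeline: quarter-scale grids and
# spoke count (64^3 reconstruction at 6 mm, ~3.9k spokes), full-FOV phantom.
# Any key omitted here falls back to the full 3 T protocol defaults.
scale: 0.25
targetSnr: 79
days: 3
scansPerDay: 3
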