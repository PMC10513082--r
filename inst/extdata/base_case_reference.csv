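arm,cost,cost_low,cost_high,life_years,ly_low,ly_high,qaly,qaly_low,qaly_high,nmb,nmb_low,nmb_high
exenatide,42114,41796,42444,23.87,23.75,23.99,12.56,12.51,12.60,117736,117159,118330
liraglutide,47026,46685,47341,23.86,23.74,23.98,12.58,12.54,12.62,113069,112496,113653
loxenatide,42092,41765,42377,24.01,23.89,24.13,12.65,12.61,12.69,118865,118268,119417
dulaglutide,42763,42479,43066,23.67,23.56,23.80,12.50,12.46,12.54,116325,115685,116908
semaglutide,46414,46103,46734,23.74,23.62,23.85,12.56,12.51,12.61,113442,112857,114029
lixisenatide,44016,43081,43737,23.79,23.67,23.91,12.52,12.48,12.56,116029,115455,116641
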