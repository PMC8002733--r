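site,latitude,longitude,lai,lai_is_range,date_start,date_end,biome,red,nir,blue,green
"BOREAS NSA/OJP, Thompson",55.92,-98.62,4.38,FALSE,1994-07-01,1994-07-31,boreal conifer,0.041,0.412,0.028,0.063
"BOREAS NSA/OBS, Thompson",55.91,-98.45,4.06,FALSE,1994-07-01,1994-07-31,boreal conifer,0.044,0.398,0.030,0.066
"BOREAS NSA, Thompson",55.91,-98.52,8.41,FALSE,1994-07-01,1994-07-31,boreal conifer,0.031,0.472,0.024,0.051
"BOREAS NSA, Thompson",55.80,-98.00,6.21,FALSE,1994-07-01,1994-07-31,boreal conifer,0.034,0.455,0.025,0.056
"BOREAS NSA, Thompson",55.75,-97.80,5.44,FALSE,1994-07-01,1994-07-31,boreal conifer,0.037,0.446,0.026,0.058
"BOREAS SSA, Prince Albert",54.06,-105.93,10.59,FALSE,1994-08-01,1994-08-31,boreal conifer,0.030,0.488,0.023,0.049
"Arakawa River, Urawa",35.83,139.62,4.24,FALSE,1985-09-01,1985-09-30,grassland,0.043,0.405,0.029,0.065
"Westvaco, Summerville, SC",33.20,-80.25,10.40,FALSE,1991-02-01,1991-02-28,tree plantation,0.030,0.484,0.023,0.050
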