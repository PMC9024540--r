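"","bio_1","bio_2","bio_3","bio_4","bio_5","bio_6","bio_7","bio_8","bio_9","bio_10","bio_11","bio_12","bio_13","bio_14","bio_15","bio_16","bio_17","bio_18","bio_19"
"bio_1",1,0.63,0.52,-0.39,0.91,0.94,-0.08,0.46,0.92,0.92,0.95,0.33,0.18,0.04,0.06,0.21,0.26,0.29,0.32
"bio_2",0.63,1,0.56,-0.05,0.71,0.51,0.25,0.18,0.5,0.67,0.55,-0.26,-0.28,-0.08,-0.21,-0.26,-0.23,-0.06,-0.03
"bio_3",0.52,0.56,1,-0.78,0.24,0.67,-0.63,0.39,0.32,0.25,0.68,0.42,0.48,-0.66,0.57,0.5,-0.36,0.6,-0.32
"bio_4",-0.39,-0.05,-0.78,1,0,-0.63,0.91,-0.4,-0.27,-0.02,-0.63,-0.7,-0.74,0.59,-0.77,-0.73,-0.01,-0.68,0.07
"bio_5",0.91,0.71,0.24,0,1,0.75,0.31,0.32,0.88,0.99,0.76,0,-0.15,0.27,-0.25,-0.12,0.27,-0.02,0.38
"bio_6",0.94,0.51,0.67,-0.63,0.75,1,-0.38,0.53,0.84,0.77,0.99,0.48,0.39,-0.14,0.31,0.41,0.19,0.44,0.19
"bio_7",-0.08,0.25,-0.63,0.91,0.31,-0.38,1,-0.32,0.01,0.26,-0.35,-0.7,-0.78,0.59,-0.81,-0.77,0.1,-0.68,0.25
"bio_8",0.46,0.18,0.39,-0.4,0.32,0.53,-0.32,1,0.23,0.34,0.51,0.41,0.38,-0.2,0.35,0.36,-0.04,0.48,-0.11
"bio_9",0.92,0.5,0.32,-0.27,0.88,0.84,0.01,0.23,1,0.88,0.85,0.24,0.06,0.2,-0.06,0.1,0.43,0.12,0.51
"bio_10",0.92,0.67,0.25,-0.02,0.99,0.77,0.26,0.34,0.88,1,0.78,0.06,-0.1,0.28,-0.23,-0.06,0.26,0.03,0.36
"bio_11",0.95,0.55,0.68,-0.63,0.76,0.99,-0.35,0.51,0.85,0.78,1,0.48,0.37,-0.14,0.29,0.4,0.21,0.45,0.23
"bio_12",0.33,-0.26,0.42,-0.7,0,0.48,-0.7,0.41,0.24,0.06,0.48,1,0.91,-0.38,0.72,0.93,0.16,0.9,0.04
"bio_13",0.18,-0.28,0.48,-0.74,-0.15,0.39,-0.78,0.38,0.06,-0.1,0.37,0.91,1,-0.65,0.91,0.99,-0.13,0.88,-0.29
"bio_14",0.04,-0.08,-0.66,0.59,0.27,-0.14,0.59,-0.2,0.2,0.28,-0.14,-0.38,-0.65,1,-0.84,-0.63,0.66,-0.6,0.68
"bio_15",0.06,-0.21,0.57,-0.77,-0.25,0.31,-0.81,0.35,-0.06,-0.23,0.29,0.72,0.91,-0.84,1,0.89,-0.32,0.76,-0.46
"bio_16",0.21,-0.26,0.5,-0.73,-0.12,0.41,-0.77,0.36,0.1,-0.06,0.4,0.93,0.99,-0.63,0.89,1,-0.12,0.9,-0.26
"bio_17",0.26,-0.23,-0.36,-0.01,0.27,0.19,0.1,-0.04,0.43,0.26,0.21,0.16,-0.13,0.66,-0.32,-0.12,1,-0.2,0.94
"bio_18",0.29,-0.06,0.6,-0.68,-0.02,0.44,-0.68,0.48,0.12,0.03,0.45,0.9,0.88,-0.6,0.76,0.9,-0.2,1,-0.25
"bio_19",0.32,-0.03,-0.32,0.07,0.38,0.19,0.25,-0.11,0.51,0.36,0.23,0.04,-0.29,0.68,-0.46,-0.26,0.94,-0.25,1
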