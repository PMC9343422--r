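metric,direction,condition,sensor_n,sensor_m,mean,sd,category
AAC,ML,EO,1,2,0.6,0.67,S
AAC,ML,EC,1,2,0.34,0.77,W
AAC,AP,EO,1,2,0.62,0.64,S
AAC,AP,EC,1,2,0.47,0.68,M
AAC,ML,EO,2,3,0,0.71,W
AAC,ML,EC,2,3,0.2,0.6,W
AAC,AP,EO,2,3,0.46,0.66,M
AAC,AP,EC,2,3,0.34,0.61,W
AAC,ML,EO,3,4,0.27,0.6,W
AAC,ML,EC,3,4,0.36,0.53,W
AAC,AP,EO,3,4,0.28,0.53,W
AAC,AP,EC,3,4,0.24,0.63,W
AAC,ML,EO,4,5,0.43,0.56,M
AAC,ML,EC,4,5,0.49,0.56,M
AAC,AP,EO,4,5,0.38,0.63,W
AAC,AP,EC,4,5,0.37,0.65,W
AAC,ML,EO,5,6,0.63,0.45,S
AAC,ML,EC,5,6,0.09,0.76,W
AAC,AP,EO,5,6,0.61,0.5,S
AAC,AP,EC,5,6,0.16,0.78,W
AAC,ML,EO,6,7,0.2,0.82,W
AAC,ML,EC,6,7,0.47,0.75,M
AAC,AP,EO,6,7,0.38,0.76,W
AAC,AP,EC,6,7,0.4,0.76,M
AAC,ML,EO,7,8,0.67,0.58,S
AAC,ML,EC,7,8,0.37,0.82,W
AAC,AP,EO,7,8,0.62,0.62,S
AAC,AP,EC,7,8,0.34,0.79,W
AAC,ML,EO,8,9,0.76,0.48,S
AAC,ML,EC,8,9,0.66,0.62,S
AAC,AP,EO,8,9,0.78,0.39,S
AAC,AP,EC,8,9,0.52,0.73,M
AAC,ML,EO,9,10,0.84,0.4,VS
AAC,ML,EC,9,10,0.73,0.55,S
AAC,AP,EO,9,10,0.86,0.3,VS
AAC,AP,EC,9,10,0.77,0.48,S
AAC,ML,EO,10,11,0.9,0.17,VS
AAC,ML,EC,10,11,0.71,0.5,S
AAC,AP,EO,10,11,0.91,0.08,VS
AAC,AP,EC,10,11,0.68,0.58,S
AAC,ML,EO,11,12,0.8,0.33,VS
AAC,ML,EC,11,12,0.68,0.53,S
AAC,AP,EO,11,12,0.83,0.28,VS
AAC,AP,EC,11,12,0.68,0.55,S
AAC,ML,EO,12,13,0.65,0.51,S
AAC,ML,EC,12,13,0.57,0.61,M
AAC,AP,EO,12,13,0.61,0.49,S
AAC,AP,EC,12,13,0.51,0.62,M
AAC,ML,EO,13,14,0.72,0.45,S
AAC,ML,EC,13,14,0.61,0.6,S
AAC,AP,EO,13,14,0.77,0.4,S
AAC,AP,EC,13,14,0.64,0.63,S
AAC,ML,EO,14,15,0.71,0.4,S
AAC,ML,EC,14,15,0.67,0.5,S
AAC,AP,EO,14,15,0.65,0.51,S
AAC,AP,EC,14,15,0.66,0.51,S
AAC,ML,EO,15,16,0.61,0.47,S
AAC,ML,EC,15,16,0.23,0.75,W
AAC,AP,EO,15,16,0.72,0.42,S
AAC,AP,EC,15,16,0.32,0.77,W
AAC,ML,EO,16,17,0.7,0.37,S
AAC,ML,EC,16,17,0.47,0.64,M
AAC,AP,EO,16,17,0.76,0.41,S
AAC,AP,EC,16,17,0.54,0.67,M
AAC,ML,EO,17,18,0.48,0.63,M
AAC,ML,EC,17,18,0.49,0.59,M
AAC,AP,EO,17,18,0.64,0.52,S
AAC,AP,EC,17,18,0.66,0.54,S
AAC,ML,EO,18,19,0.17,0.67,W
AAC,ML,EC,18,19,0.51,0.47,M
AAC,AP,EO,18,19,0.38,0.62,W
AAC,AP,EC,18,19,0.54,0.51,M
AAC,ML,EO,19,20,0.16,0.63,W
AAC,ML,EC,19,20,0.17,0.61,W
AAC,AP,EO,19,20,0.24,0.67,W
AAC,AP,EC,19,20,0.02,0.63,W
AAC,ML,EO,20,21,0.43,0.43,M
AAC,ML,EC,20,21,0.42,0.53,M
AAC,AP,EO,20,21,0.39,0.47,W
AAC,AP,EC,20,21,0.36,0.56,W
AAC,ML,EO,21,22,0.47,0.48,M
AAC,ML,EC,21,22,0.44,0.51,M
AAC,AP,EO,21,22,0.41,0.53,M
AAC,AP,EC,21,22,0.39,0.63,W
APLV,ML,EO,1,2,0.56,0.62,M
APLV,ML,EC,1,2,0.32,0.71,W
APLV,AP,EO,1,2,0.59,0.57,M
APLV,AP,EC,1,2,0.46,0.65,M
APLV,ML,EO,2,3,0.06,0.63,W
APLV,ML,EC,2,3,0.18,0.57,W
APLV,AP,EO,2,3,0.36,0.64,W
APLV,AP,EC,2,3,0.3,0.58,W
APLV,ML,EO,3,4,0.19,0.6,W
APLV,ML,EC,3,4,0.37,0.49,W
APLV,AP,EO,3,4,0.29,0.54,W
APLV,AP,EC,3,4,0.25,0.55,W
APLV,ML,EO,4,5,0.38,0.52,W
APLV,ML,EC,4,5,0.43,0.54,M
APLV,AP,EO,4,5,0.34,0.6,W
APLV,AP,EC,4,5,0.33,0.59,W
APLV,ML,EO,5,6,0.56,0.43,M
APLV,ML,EC,5,6,0.1,0.73,W
APLV,AP,EO,5,6,0.59,0.44,M
APLV,AP,EC,5,6,0.14,0.73,W
APLV,ML,EO,6,7,0.17,0.78,W
APLV,ML,EC,6,7,0.45,0.72,M
APLV,AP,EO,6,7,0.4,0.72,M
APLV,AP,EC,6,7,0.39,0.71,W
APLV,ML,EO,7,8,0.64,0.78,S
APLV,ML,EC,7,8,0.36,0.78,W
APLV,AP,EO,7,8,0.63,0.59,S
APLV,AP,EC,7,8,0.3,0.74,W
APLV,ML,EO,8,9,0.72,0.44,S
APLV,ML,EC,8,9,0.64,0.59,S
APLV,AP,EO,8,9,0.77,0.37,S
APLV,AP,EC,8,9,0.46,0.69,M
APLV,ML,EO,9,10,0.8,0.37,VS
APLV,ML,EC,9,10,0.7,0.5,S
APLV,AP,EO,9,10,0.84,0.26,VS
APLV,AP,EC,9,10,0.73,0.4,S
APLV,ML,EO,10,11,0.85,0.17,VS
APLV,ML,EC,10,11,0.67,0.47,S
APLV,AP,EO,10,11,0.86,0.1,VS
APLV,AP,EC,10,11,0.63,0.54,S
APLV,ML,EO,11,12,0.73,0.31,S
APLV,ML,EC,11,12,0.62,0.51,S
APLV,AP,EO,11,12,0.77,0.26,S
APLV,AP,EC,11,12,0.64,0.49,S
APLV,ML,EO,12,13,0.61,0.42,S
APLV,ML,EC,12,13,0.51,0.56,M
APLV,AP,EO,12,13,0.5,0.49,M
APLV,AP,EC,12,13,0.49,0.55,M
APLV,ML,EO,13,14,0.61,0.42,S
APLV,ML,EC,13,14,0.57,0.55,M
APLV,AP,EO,13,14,0.72,0.35,S
APLV,AP,EC,13,14,0.61,0.57,S
APLV,ML,EO,14,15,0.6,0.38,S
APLV,ML,EC,14,15,0.62,0.46,S
APLV,AP,EO,14,15,0.6,0.43,S
APLV,AP,EC,14,15,0.6,0.48,S
APLV,ML,EO,15,16,0.52,0.46,M
APLV,ML,EC,15,16,0.17,0.7,W
APLV,AP,EO,15,16,0.64,0.38,S
APLV,AP,EC,15,16,0.28,0.72,W
APLV,ML,EO,16,17,0.65,0.33,S
APLV,ML,EC,16,17,0.43,0.6,M
APLV,AP,EO,16,17,0.74,0.34,S
APLV,AP,EC,16,17,0.52,0.62,M
APLV,ML,EO,17,18,0.44,0.58,M
APLV,ML,EC,17,18,0.44,0.54,M
APLV,AP,EO,17,18,0.59,0.5,M
APLV,AP,EC,17,18,0.59,0.54,M
APLV,ML,EO,18,19,0.16,0.6,W
APLV,ML,EC,18,19,0.49,0.44,M
APLV,AP,EO,18,19,0.3,0.59,W
APLV,AP,EC,18,19,0.51,0.47,M
APLV,ML,EO,19,20,0.13,0.58,W
APLV,ML,EC,19,20,0.22,0.56,W
APLV,AP,EO,19,20,0.18,0.59,W
APLV,AP,EC,19,20,0,0.6,W
APLV,ML,EO,20,21,0.4,0.43,M
APLV,ML,EC,20,21,0.38,0.5,W
APLV,AP,EO,20,21,0.35,0.47,W
APLV,AP,EC,20,21,0.28,0.54,W
APLV,ML,EO,21,22,0.46,0.42,M
APLV,ML,EC,21,22,0.41,0.48,M
APLV,AP,EO,21,22,0.35,0.48,W
APLV,AP,EC,21,22,0.35,0.58,W
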