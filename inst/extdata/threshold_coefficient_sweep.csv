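K_time,K_amp,SEN,pos_pred,ACC
0.36,0.1,98.65,80.94,80.06
0.36,0.15,98.93,87.29,86.47
0.36,0.2,98.68,90.23,89.16
0.36,0.25,97.87,92.38,90.56
0.36,0.3,96.45,93.69,90.57
0.36,0.35,93.87,94.55,89.05
0.36,0.4,90.78,96.56,87.94
0.36,0.45,87.54,97.89,85.92
0.36,0.5,84.16,98.67,83.22
0.39,0.1,96.42,85.94,83.28
0.39,0.15,97.59,91.24,89.24
0.39,0.2,98.05,93.64,91.93
0.39,0.25,97.61,94.99,92.83
0.39,0.3,96.31,95.58,92.2
0.39,0.35,93.79,96.37,90.59
0.39,0.4,90.72,98.08,89.14
0.39,0.45,87.51,99.04,86.78
0.39,0.5,84.14,99.39,83.71
0.42,0.1,95.7,89.98,86.48
0.42,0.15,97.2,94.56,92.05
0.42,0.2,97.8,96.42,94.38
0.42,0.25,97.43,97.4,94.96
0.42,0.3,96.18,97.79,94.13
0.42,0.35,93.68,98.27,92.16
0.42,0.4,90.64,98.98,89.8
0.42,0.45,87.44,99.38,86.97
0.42,0.5,84.09,99.56,83.78
0.45,0.1,94.57,92.51,90.85
0.45,0.15,96.47,96.73,96.42
0.45,0.2,97.17,98.28,98.54
0.45,0.25,99.39,99.49,98.89
0.45,0.3,95.73,99.09,97.9
0.45,0.35,93.36,99.26,95.72
0.45,0.4,90.42,99.42,92.94
0.45,0.45,87.28,99.54,89.93
0.45,0.5,83.94,99.63,86.68
0.48,0.1,93.84,93.54,88.13
0.48,0.15,95.87,97.2,93.29
0.48,0.2,96.63,98.59,95.32
0.48,0.25,96.38,99.07,95.52
0.48,0.3,95.26,99.26,94.58
0.48,0.35,92.9,99.38,92.37
0.48,0.4,89.97,99.48,89.55
0.48,0.45,86.86,99.56,86.53
0.48,0.5,83.57,99.64,83.31
0.51,0.1,93.06,94.04,87.87
0.51,0.15,95.28,97.45,92.96
0.51,0.2,96.08,98.68,94.86
0.51,0.25,95.83,99.1,95.01
0.51,0.3,94.69,99.28,94.04
0.51,0.35,92.3,99.39,91.78
0.51,0.4,89.35,99.49,88.94
0.51,0.45,86.24,99.56,85.92
0.51,0.5,82.98,99.64,82.73
0.54,0.1,92.1,94.26,87.21
0.54,0.15,94.59,97.63,92.47
0.54,0.2,95.41,98.73,94.25
0.54,0.25,95.15,99.12,94.36
0.54,0.3,94.02,99.3,93.4
0.54,0.35,91.66,99.41,91.16
0.54,0.4,88.73,99.5,88.34
0.54,0.45,85.66,99.57,85.35
0.54,0.5,82.43,99.65,82.19
0.57,0.1,90.9,94.31,86.17
0.57,0.15,93.54,97.68,91.51
0.57,0.2,94.41,98.76,93.3
0.57,0.25,94.14,99.15,93.38
0.57,0.3,93.03,99.31,92.44
0.57,0.35,90.73,99.42,90.25
0.57,0.4,87.86,99.51,87.48
0.57,0.45,84.85,99.57,84.54
0.57,0.5,81.65,99.65,81.42
0.6,0.1,89.1,94.28,84.53
0.6,0.15,91.87,97.67,89.9
0.6,0.2,92.8,98.76,91.73
0.6,0.25,92.6,99.16,91.88
0.6,0.3,91.58,99.32,91.01
0.6,0.35,89.46,99.43,89.0
0.6,0.4,86.85,99.52,86.48
0.6,0.45,83.99,99.58,83.69
0.6,0.5,80.9,99.65,80.68
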