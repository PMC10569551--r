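metric,method,setting,stack,value
dsc,unet,threshold_t0.45,1,56.38
dsc,unet,threshold_t0.45,2,70.32
dsc,unet,threshold_t0.45,3,58.85
dsc,unet,threshold_t0.45,4,61.84
dsc,unet,threshold_t0.45,5,67.63
dsc,unet,threshold_t0.45,6,55.41
dsc,unet,threshold_t0.45,7,58.59
dsc,unet,threshold_t0.45,8,61.73
dsc,vesselness,threshold,1,47.03
dsc,vesselness,threshold,2,56.90
dsc,vesselness,threshold,3,34.82
dsc,vesselness,threshold,4,37.40
dsc,vesselness,threshold,5,65.40
dsc,vesselness,threshold,6,33.86
dsc,vesselness,threshold,7,41.60
dsc,vesselness,threshold,8,34.07
recall,unet,threshold_t0.3,1,74.91
recall,unet,threshold_t0.3,2,89.66
recall,unet,threshold_t0.3,3,84.36
recall,unet,threshold_t0.3,4,81.18
recall,unet,threshold_t0.3,5,90.20
recall,unet,threshold_t0.3,6,64.93
recall,unet,threshold_t0.3,7,79.06
recall,unet,threshold_t0.3,8,81.61
precision,unet,threshold_t0.6,1,64.27
precision,unet,threshold_t0.6,2,78.72
precision,unet,threshold_t0.6,3,74.84
precision,unet,threshold_t0.6,4,79.36
precision,unet,threshold_t0.6,5,79.25
precision,unet,threshold_t0.6,6,86.18
precision,unet,threshold_t0.6,7,75.81
precision,unet,threshold_t0.6,8,78.25
precision,unet,threshold_t0.45,1,52.41
recall,unet,threshold_t0.45,1,61.01
tnr,unet,threshold_t0.45,1,99.93
prevalence_fg,dataset,brain,1,0.132
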