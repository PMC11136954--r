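table,method,class,precision,recall,f1,oa,iou,miou,fwiou
ablation,erfnet-ce,background,98.41,98.29,98.35,96.58,96.75,86.34,93.59
ablation,erfnet-ce,bean_seedling,87.48,87.21,87.34,96.58,77.54,86.34,93.59
ablation,erfnet-ce,weed,91.38,92.09,91.73,96.58,84.73,86.34,93.59
ablation,erf-psa-ce,background,98.55,98.59,98.57,96.94,97.19,87.49,94.24
ablation,erf-psa-ce,bean_seedling,89.17,87.83,88.49,96.94,79.36,87.49,94.24
ablation,erf-psa-ce,weed,92.19,92.68,92.43,96.94,85.93,87.49,94.24
ablation,erf-psa-doubleloss,background,98.75,98.49,98.62,97.04,97.27,87.81,94.41
ablation,erf-psa-doubleloss,bean_seedling,88.65,88.68,88.66,97.04,79.64,87.81,94.41
ablation,erf-psa-doubleloss,weed,92.15,93.40,92.77,97.04,86.51,87.81,94.41
ablation,erf-psa-doubleloss-simam,background,98.76,98.70,98.73,97.14,97.49,87.92,94.61
ablation,erf-psa-doubleloss-simam,bean_seedling,89.36,87.83,88.59,97.14,79.51,87.92,94.61
ablation,erf-psa-doubleloss-simam,weed,92.38,93.43,92.90,97.14,86.74,87.92,94.61
ablation,epanet,background,98.89,98.70,98.79,97.23,97.62,88.25,94.78
ablation,epanet,bean_seedling,90.90,87.26,89.04,97.23,80.25,88.25,94.78
ablation,epanet,weed,91.61,94.39,92.98,97.23,86.88,88.25,94.78
comparison,icnet,background,98.02,97.18,97.60,95.15,95.30,81.20,91.05
comparison,icnet,bean_seedling,79.45,83.73,81.53,95.15,68.82,81.20,91.05
comparison,icnet,weed,87.66,89.51,88.58,95.15,79.49,81.20,91.05
comparison,unet,background,98.52,97.83,98.17,95.89,96.42,83.07,92.40
comparison,unet,bean_seedling,83.16,83.37,83.26,95.89,71.33,83.07,92.40
comparison,unet,weed,88.19,91.43,89.78,95.89,81.46,83.07,92.40
comparison,fcn,background,98.00,97.15,97.57,95.25,95.26,81.92,91.22
comparison,fcn,bean_seedling,82.14,83.25,82.69,95.25,70.49,81.92,91.22
comparison,fcn,weed,97.17,90.70,93.82,95.25,80.02,81.92,91.22
comparison,deeplabv3,background,98.02,97.41,97.71,95.57,95.53,83.18,91.78
comparison,deeplabv3,bean_seedling,83.39,85.09,84.23,95.57,72.76,83.18,91.78
comparison,deeplabv3,weed,88.65,90.71,89.67,95.57,81.27,83.18,91.78
comparison,fast-scnn,background,98.41,97.67,98.04,95.87,96.16,83.44,92.33
comparison,fast-scnn,bean_seedling,82.25,85.65,83.92,95.87,72.28,83.44,92.33
comparison,fast-scnn,weed,89.10,90.98,90.03,95.87,81.87,83.44,92.33
comparison,deeplabv3plus,background,98.47,97.87,98.17,96.19,96.42,84.70,92.88
comparison,deeplabv3plus,bean_seedling,83.80,87.12,85.43,96.19,74.56,84.70,92.88
comparison,deeplabv3plus,weed,90.11,91.45,90.78,96.19,83.10,84.70,92.88
comparison,erfnet,background,98.41,98.29,98.35,96.58,96.75,86.34,93.59
comparison,erfnet,bean_seedling,87.48,87.21,87.34,96.58,77.54,86.34,93.59
comparison,erfnet,weed,91.38,92.09,91.73,96.58,84.73,86.34,93.59
comparison,epanet,background,98.89,98.70,98.80,97.23,97.62,88.25,94.78
comparison,epanet,bean_seedling,90.90,87.26,89.04,97.23,80.25,88.25,94.78
comparison,epanet,weed,91.61,94.39,92.98,97.23,86.88,88.25,94.78
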