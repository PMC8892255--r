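{
  "description": "Cohort-derived diagnostic ranges for the physiological parameters and dimensionless subsystem indices of the five-compartment glucose-insulin model. 'healthy' is the central 90% interval of the healthy-cohort log-logistic fit; 'undesirable' extends from the equal-density threshold side boundary to the healthy-interval limit on the non-healthy side; 'abnormal' continues beyond it. 'direction' is the side on which non-health lies.",
  "rows": [
    {"index": "k_js",  "process": "Digestive motility",      "units": "min^-1",        "healthy": [0.0198, 0.244],    "undesirable": [0.01, 0.0198],      "abnormal_direction": "below", "abnormal_bound": 0.01},
    {"index": "tau",   "process": "Digestive motility",      "units": "min",           "healthy": [72, 111],          "undesirable": [45, 72],            "abnormal_direction": "below", "abnormal_bound": 45},
    {"index": "Pi_S",  "process": "Digestive motility",      "units": "-",             "healthy": [0.396, 47.6],      "undesirable": [0.0013, 0.396],     "abnormal_direction": "below", "abnormal_bound": 0.0013},
    {"index": "k_lg",  "process": "Glucose absorption",      "units": "min^-1",        "healthy": [0.00371, 0.602],   "undesirable": [0.602, 1.62],       "abnormal_direction": "above", "abnormal_bound": 1.62},
    {"index": "Pi_N",  "process": "Incretin potency",        "units": "-",             "healthy": [0.232, 3.84],      "undesirable": [8.12e-4, 0.232],    "abnormal_direction": "below", "abnormal_bound": 8.12e-4},
    {"index": "eta",   "process": "Glucose distribution",    "units": "L^-3",          "healthy": [0.0145, 0.178],    "undesirable": [0.178, 6.97],       "abnormal_direction": "above", "abnormal_bound": 6.97},
    {"index": "Pi_D",  "process": "Glucose distribution",    "units": "-",             "healthy": [1.20, 15.4],       "undesirable": [15.4, 550],         "abnormal_direction": "above", "abnormal_bound": 550},
    {"index": "k_xgi", "process": "Tisular glucose uptake",  "units": "min^-1 pM^-1",  "healthy": [9.41e-6, 0.00259], "undesirable": [5.67e-9, 9.41e-6],  "abnormal_direction": "below", "abnormal_bound": 5.67e-9},
    {"index": "Pi_B",  "process": "Tisular glucose uptake",  "units": "-",             "healthy": [0.00204, 159],     "undesirable": [6.42e-7, 0.00204],  "abnormal_direction": "below", "abnormal_bound": 6.42e-7},
    {"index": "Pi_X",  "process": "Tisular glucose uptake",  "units": "-",             "healthy": [0.00866, 0.395],   "undesirable": [3.59e-7, 0.00866],  "abnormal_direction": "below", "abnormal_bound": 3.59e-7},
    {"index": "Pi_I",  "process": "Pancreatic response",     "units": "-",             "healthy": [0.394, 19.0],      "undesirable": [0.00871, 0.394],    "abnormal_direction": "below", "abnormal_bound": 0.00871},
    {"index": "Pi_R",  "process": "Hepatic response",        "units": "-",             "healthy": [0.00933, 41.0],    "undesirable": [41.0, 134],         "abnormal_direction": "above", "abnormal_bound": 134},
    {"index": "G_b",   "process": "Effective control levels","units": "mM",            "healthy": [4.10, 5.03],       "undesirable": [5.03, 5.29],        "abnormal_direction": "above", "abnormal_bound": 5.29},
    {"index": "I_b",   "process": "Effective control levels","units": "pM",            "healthy": [13.1, 47.9],       "undesirable": [47.9, 68.6],        "abnormal_direction": "above", "abnormal_bound": 68.6}
  ]
}
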