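cancer_code	cancer_name	has_stage
aml	Acute myelogenous leukemia	FALSE
bladder	Bladder cancer	FALSE
brainlgg	Brain low grade gliomas	FALSE
gbm	Glioblastoma multiforme	FALSE
headneck	Head and neck cancer	FALSE
sarcoma	Sarcoma	FALSE
breast	Breast cancer	TRUE
cervical	Cervical cancer	TRUE
colorectal	Colorectal cancer	TRUE
liver	Liver cancer	TRUE
lung	Lung adenocarcinoma	TRUE
lungsc	Lung squamous cell cancer	TRUE
melanoma	Melanoma	TRUE
ovarian	Ovarian cancer	TRUE
rcc	Renal clear cell cancer	TRUE
rpc	Renal papillary cancer	TRUE
stomach	Stomach cancer	TRUE
uterine	Uterine cancer	TRUE
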