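axis	priority	pattern	label
category	60	glioblastoma|astrocytoma|oligodendroglioma|\bglioma|meningioma|schwannoma|ependymoma|medulloblastoma|pituitary adenoma|craniopharyngioma	primary brain tumour
category	50	metasta|carcinoma|melanoma|sarcoma	probable metastasis
category	40	abscess|demyelinat|encephalitis|radiation necrosis|gliosis	other brain lesions
category	30	arachnoid cyst|epidermoid cyst|colloid cyst|lipoma	miscellaneous lesions
category	20	infarct|ha?ematoma|aneurysm|arteriovenous malformation|cavernoma|ha?emorrhage	brain cardiovascular disease
subtype	40	(?<!non-)small cell	SCLC
subtype	30	adenocarcinoma	AC
subtype	20	squamous cell	SCC
subtype	10	non-small cell	NSCLC-NOS
primary_site	60	\blung|pulmonary|bronch	lung
primary_site	50	breast|mammary	breast
primary_site	40	melanoma	melanoma
primary_site	30	colorect|\bcolon\b|rectal	colorectal
primary_site	20	renal|kidney	kidney
location	60	front	frontal
location	50	pariet	parietal
location	40	tempor	temporal
location	30	occipit	occipital
location	20	cerebell	cerebellum
location	10	brainstem|thalam|basal ganglia|dural?\b|ventric|callosum|pineal|sellar|\bpons\b|medulla|midbrain|spinal	other
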