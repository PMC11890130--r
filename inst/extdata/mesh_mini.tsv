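descriptor	tree_numbers	entry_terms
Arthritis	C05.550.114	arthritis
Arthritis, Rheumatoid	C05.550.114.154;C17.300.775.099	rheumatoid arthritis
Osteoarthritis	C05.550.114.606	osteoarthritis|degenerative arthritis
Joint Diseases	C05.550	joint disease|joint diseases
Hypertension	C14.907.489	hypertension|high blood pressure
Blood Pressure	G09.330.380.076	blood pressure
Antihypertensive Agents	D27.505.954.411.097	antihypertensive|antihypertensives|blood pressure medication
Cardiovascular Diseases	C14	cardiovascular disease|cardiovascular diseases|heart disease
COVID-19	C01.925.782.600.550.200.163	covid-19|covid|coronavirus disease 2019|sars-cov-2 infection
Coronavirus Infections	C01.925.782.600.550.200	coronavirus infection|coronavirus infections
Pulmonary Disease, Chronic Obstructive	C08.381.495.389	chronic obstructive pulmonary disease|copd|chronic obstructive lung disease
Lung Neoplasms	C04.588.894.797.520;C08.381.540	lung cancer|lung neoplasm|lung neoplasms|lung carcinoma|pulmonary cancer
Prostatic Neoplasms	C04.588.945.440.770;C12.294.260.750	prostate cancer|prostatic neoplasm|prostatic neoplasms|prostate carcinoma
Neoplasms	C04	cancer|cancers|neoplasm|neoplasms|tumor|tumour
Diabetes Mellitus	C18.452.394.750	diabetes|diabetes mellitus
Diabetes Mellitus, Type 2	C18.452.394.750.149	type 2 diabetes|diabetes mellitus type 2|non-insulin-dependent diabetes
Insulin	D06.472.699.587.200	insulin
Blood Glucose	D09.400.410	blood glucose|blood sugar
Prevalence	E05.318.308.985.525;N05.715.360.750.625	prevalence|prevalence rate
Incidence	E05.318.308.985.500;N05.715.360.750.500	incidence|incidence rate
Risk Factors	E05.318.740.600.800;N05.715.360.750.750	risk factor|risk factors
Mortality	E05.318.308.985.550;N01.224.935.597	mortality|death rate
Epidemiologic Studies	E05.318.760	epidemiologic study|epidemiological studies
Public Health	H02.403.720	public health
Signs and Symptoms	C23.888	signs and symptoms
Pain	C23.888.592.612;F02.830.816.444	pain
Fatigue	C23.888.369	fatigue|tiredness
Dyspnea	C08.618.326;C23.888.852.371	dyspnea|shortness of breath|breathlessness
Cough	C08.618.248;C23.888.852.293	cough|coughing
Fever	C23.888.119.344	fever
Inflammation	C23.550.470	inflammation
Edema	C23.888.277	edema|swelling
Muscle Weakness	C05.651.515;C23.888.592.608	muscle weakness|weakness
Therapeutics	E02	therapy|therapeutics|treatment|treatments
Drug Therapy	E02.319	drug therapy|drug treatment|medication|medications
Surgical Procedures, Operative	E04	surgery|surgical intervention|operation|surgical procedure
Diagnosis	E01	diagnosis
Physical Examination	E01.370.600	physical examination|medical examination|clinical examination
Mass Screening	E01.370.500.580	screening|mass screening
Early Detection of Cancer	E01.390.200	early detection of cancer|cancer screening
Spirometry	E01.370.386.700.750	spirometry
Vaccination	E02.095.465.425	vaccination|immunization|vaccine
Exercise	G11.427.410.698.277	exercise|physical activity
Diet	G07.203.650.240	diet|dietary
Smoking	F01.145.466.753	smoking|tobacco use
Biopsy	E01.370.225.500	biopsy
Prostate-Specific Antigen	D08.811.277.656.300	prostate-specific antigen|psa test|psa
Rehabilitation	E02.760	rehabilitation
Prognosis	E01.789	prognosis
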