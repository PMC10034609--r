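local_code,local_system,target_code,target_system,display
D001,HIS-DIAG,U07.1,ICD-10-CM,COVID-19
D002,HIS-DIAG,J12.82,ICD-10-CM,pneumonia due to coronavirus disease 2019
D003,HIS-DIAG,H40.9,ICD-10-CM,unspecified glaucoma
D004,HIS-DIAG,I10,ICD-10-CM,essential (primary) hypertension
D005,HIS-DIAG,E11.9,ICD-10-CM,type 2 diabetes mellitus without complications
D006,HIS-DIAG,J44.9,ICD-10-CM,chronic obstructive pulmonary disease unspecified
D007,HIS-DIAG,N39.0,ICD-10-CM,urinary tract infection site not specified
D008,HIS-DIAG,I21.9,ICD-10-CM,acute myocardial infarction unspecified
D009,HIS-DIAG,I50.9,ICD-10-CM,heart failure unspecified
D010,HIS-DIAG,J18.9,ICD-10-CM,pneumonia unspecified organism
D011,HIS-DIAG,A41.9,ICD-10-CM,sepsis unspecified organism
D012,HIS-DIAG,K21.9,ICD-10-CM,gastro-esophageal reflux disease without esophagitis
D013,HIS-DIAG,E78.5,ICD-10-CM,hyperlipidemia unspecified
D014,HIS-DIAG,F03.90,ICD-10-CM,unspecified dementia without behavioral disturbance
D015,HIS-DIAG,G47.33,ICD-10-CM,obstructive sleep apnea
D016,HIS-DIAG,D64.9,ICD-10-CM,anemia unspecified
D017,HIS-DIAG,N17.9,ICD-10-CM,acute kidney failure unspecified
D018,HIS-DIAG,J96.00,ICD-10-CM,acute respiratory failure
D019,HIS-DIAG,R05.9,ICD-10-CM,cough unspecified
D020,HIS-DIAG,R50.9,ICD-10-CM,fever unspecified
D021,HIS-DIAG,R06.02,ICD-10-CM,shortness of breath
D022,HIS-DIAG,M54.5,ICD-10-CM,low back pain
D023,HIS-DIAG,I48.91,ICD-10-CM,unspecified atrial fibrillation
D024,HIS-DIAG,E87.1,ICD-10-CM,hypo-osmolality and hyponatremia
D025,HIS-DIAG,K92.2,ICD-10-CM,gastrointestinal hemorrhage unspecified
D026,HIS-DIAG,L03.90,ICD-10-CM,cellulitis unspecified
D027,HIS-DIAG,B34.9,ICD-10-CM,viral infection unspecified
D028,HIS-DIAG,J45.909,ICD-10-CM,unspecified asthma uncomplicated
D029,HIS-DIAG,I63.9,ICD-10-CM,cerebral infarction unspecified
D030,HIS-DIAG,G40.909,ICD-10-CM,epilepsy unspecified
D031,HIS-DIAG,C34.90,ICD-10-CM,malignant neoplasm of unspecified part of bronchus or lung
D032,HIS-DIAG,K80.20,ICD-10-CM,calculus of gallbladder without cholecystitis
D033,HIS-DIAG,N18.3,ICD-10-CM,chronic kidney disease stage 3
D034,HIS-DIAG,E86.0,ICD-10-CM,dehydration
D035,HIS-DIAG,R55,ICD-10-CM,syncope and collapse
D036,HIS-DIAG,J20.9,ICD-10-CM,acute bronchitis unspecified
D037,HIS-DIAG,I82.409,ICD-10-CM,acute embolism and thrombosis of unspecified deep veins of lower extremity
D038,HIS-DIAG,I26.99,ICD-10-CM,other pulmonary embolism without acute cor pulmonale
D039,HIS-DIAG,K57.30,ICD-10-CM,diverticulosis of large intestine
D040,HIS-DIAG,M17.9,ICD-10-CM,osteoarthritis of knee unspecified
D041,HIS-DIAG,H25.9,ICD-10-CM,unspecified age-related cataract
D042,HIS-DIAG,E03.9,ICD-10-CM,hypothyroidism unspecified
D043,HIS-DIAG,F32.9,ICD-10-CM,major depressive disorder single episode unspecified
D044,HIS-DIAG,G20,ICD-10-CM,Parkinson disease
D045,HIS-DIAG,K35.80,ICD-10-CM,unspecified acute appendicitis
D046,HIS-DIAG,N40.0,ICD-10-CM,benign prostatic hyperplasia without lower urinary tract symptoms
D047,HIS-DIAG,R51.9,ICD-10-CM,headache unspecified
D048,HIS-DIAG,E66.9,ICD-10-CM,obesity unspecified
D049,HIS-DIAG,I95.9,ICD-10-CM,hypotension unspecified
D050,HIS-DIAG,R41.82,ICD-10-CM,altered mental status unspecified
C001,HIS-CLIN,8310-5,LOINC,body temperature
C002,HIS-CLIN,8867-4,LOINC,heart rate
C003,HIS-CLIN,9279-1,LOINC,respiratory rate
C004,HIS-CLIN,8480-6,LOINC,systolic blood pressure
C005,HIS-CLIN,8462-4,LOINC,diastolic blood pressure
C006,HIS-CLIN,2708-6,LOINC,oxygen saturation in arterial blood
C007,HIS-CLIN,29463-7,LOINC,body weight
C008,HIS-CLIN,8302-2,LOINC,body height
C009,HIS-CLIN,9269-2,LOINC,glasgow coma score total
C010,HIS-CLIN,3150-0,LOINC,inhaled oxygen concentration
L001,HIS-LAB,2345-7,LOINC,glucose in serum or plasma
L002,HIS-LAB,2160-0,LOINC,creatinine in serum or plasma
L003,HIS-LAB,3094-0,LOINC,urea nitrogen in serum or plasma
L004,HIS-LAB,2951-2,LOINC,sodium in serum or plasma
L005,HIS-LAB,2823-3,LOINC,potassium in serum or plasma
L006,HIS-LAB,2075-0,LOINC,chloride in serum or plasma
L007,HIS-LAB,1975-2,LOINC,bilirubin total in serum or plasma
L008,HIS-LAB,1742-6,LOINC,alanine aminotransferase in serum or plasma
L009,HIS-LAB,1920-8,LOINC,aspartate aminotransferase in serum or plasma
L010,HIS-LAB,6768-6,LOINC,alkaline phosphatase in serum or plasma
L011,HIS-LAB,2532-0,LOINC,lactate dehydrogenase in serum or plasma
L012,HIS-LAB,1988-5,LOINC,C reactive protein in serum or plasma
L013,HIS-LAB,2276-4,LOINC,ferritin in serum or plasma
L014,HIS-LAB,48065-7,LOINC,fibrin D-dimer FEU in platelet poor plasma
L015,HIS-LAB,6690-2,LOINC,leukocytes in blood
L016,HIS-LAB,789-8,LOINC,erythrocytes in blood
L017,HIS-LAB,718-7,LOINC,hemoglobin in blood
L018,HIS-LAB,4544-3,LOINC,hematocrit of blood
L019,HIS-LAB,777-3,LOINC,platelets in blood
L020,HIS-LAB,14979-9,LOINC,activated partial thromboplastin time
M001,HIS-DRUG,387517004,SNOMED CT,paracetamol
M002,HIS-DRUG,387458008,SNOMED CT,aspirin
M003,HIS-DRUG,372756006,SNOMED CT,warfarin
M004,HIS-DRUG,372567009,SNOMED CT,dexamethasone
M005,HIS-DRUG,387562000,SNOMED CT,enoxaparin
M006,HIS-DRUG,386963006,SNOMED CT,remdesivir
M007,HIS-DRUG,372687004,SNOMED CT,amoxicillin
M008,HIS-DRUG,387531004,SNOMED CT,azithromycin
M009,HIS-DRUG,386864001,SNOMED CT,furosemide
M010,HIS-DRUG,386872004,SNOMED CT,omeprazole
P001,HIS-PROC,40617009,SNOMED CT,artificial respiration
P002,HIS-PROC,57485005,SNOMED CT,oxygen therapy
P003,HIS-PROC,265764009,SNOMED CT,renal dialysis
P004,HIS-PROC,71651007,SNOMED CT,mechanical ventilation weaning
P005,HIS-PROC,392230005,SNOMED CT,insertion of central venous catheter
P006,HIS-PROC,399208008,SNOMED CT,plain chest X-ray
P007,HIS-PROC,77477000,SNOMED CT,computed tomography of thorax
P008,HIS-PROC,447365002,SNOMED CT,insertion of urinary catheter
SEX-M,HIS-SEX,248153007,SNOMED CT,male
SEX-F,HIS-SEX,248152002,SNOMED CT,female
LLST1,HIS-LLST,304253006,SNOMED CT,not for resuscitation
LLST2,HIS-LLST,439569004,SNOMED CT,resuscitation status unknown
ER,HIS-EPI,ER,local,emergency room episode
HOSP,HIS-EPI,HOSP,local,hospitalization episode
HOME,HIS-DISCH,HOME,local,discharge to home
TRANSFER,HIS-DISCH,TRANSFER,local,transfer to another facility
DEATH,HIS-DISCH,DEATH,local,death
PO,HIS-ROUTE,PO,local,oral route
IV,HIS-ROUTE,IV,local,intravenous route
SC,HIS-ROUTE,SC,local,subcutaneous route
U01,HIS-UNIT,U01,local,emergency department
U02,HIS-UNIT,U02,local,general medicine ward
U03,HIS-UNIT,U03,local,pneumology ward
U04,HIS-UNIT,U04,local,intensive care unit
U05,HIS-UNIT,U05,local,respiratory intensive care unit
U06,HIS-UNIT,U06,local,surgery ward
U07,HIS-UNIT,U07,local,geriatrics ward
U08,HIS-UNIT,U08,local,day hospital
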