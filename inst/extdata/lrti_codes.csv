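infection,dialect,code,description
lrti,ICD9,466.0,Acute bronchitis
lrti,ICD9,466.1,Acute bronchitis
lrti,ICD9,466.11,Acute bronchitis
lrti,ICD9,466.19,Acute bronchitis
lrti,ICD9,466.2,Acute bronchiolitis
lrti,ICD9,510,Empyema
lrti,ICD9,510.0,Empyema
lrti,ICD9,510.9,Empyema
lrti,ICD9,511.1,Pleurisy with effusion
lrti,ICD9,513.0,Abscess of lung and mediastinum
lrti,ICD9,513.1,Abscess of lung and mediastinum
lrti,ICD9,031.0,Pulmonary disease caused by Mycobacterium
lrti,ICD9,464.10,Acute laryngotracheitis and tracheitis
lrti,ICD9,464.11,Acute laryngotracheitis and tracheitis
lrti,ICD9,464.2,Acute laryngotracheitis and tracheitis
lrti,ICD9,464.21,Acute laryngotracheitis and tracheitis
lrti,ICD10,J20.0,Acute bronchitis
lrti,ICD10,J20.1,Acute bronchitis
lrti,ICD10,J20.2,Acute bronchitis
lrti,ICD10,J20.3,Acute bronchitis
lrti,ICD10,J20.4,Acute bronchitis
lrti,ICD10,J20.5,Acute bronchitis
lrti,ICD10,J20.6,Acute bronchitis
lrti,ICD10,J20.7,Acute bronchitis
lrti,ICD10,J20.8,Acute bronchitis
lrti,ICD10,J20.9,Acute bronchitis
lrti,ICD10,J21.0,Acute bronchiolitis
lrti,ICD10,J21.1,Acute bronchiolitis
lrti,ICD10,J21.8,Acute bronchiolitis
lrti,ICD10,J21.9,Acute bronchiolitis
lrti,ICD10,J86.0,Empyema
lrti,ICD10,J86.9,Empyema
lrti,ICD10,J90,Pleurisy with effusion
lrti,ICD10,J94.2,Pleurisy with effusion
lrti,ICD10,J85.0,Abscess of lung and mediastinum
lrti,ICD10,J85.1,Abscess of lung and mediastinum
lrti,ICD10,J85.2,Abscess of lung and mediastinum
lrti,ICD10,J85.3,Abscess of lung and mediastinum
lrti,ICD10,A31.0,Pulmonary disease caused by Mycobacterium
lrti,ICD10,J04.10,Acute laryngotracheitis and tracheitis
lrti,ICD10,J04.11,Acute laryngotracheitis and tracheitis
lrti,ICD10,J05.0,Acute laryngotracheitis and tracheitis
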