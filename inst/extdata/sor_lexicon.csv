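category,term
education,education
education,training
education,workshop
education,curriculum
education,outreach
prevention,prevention
prevention,harm reduction
prevention,screening
prevention,sbirt
prevention,drug disposal
prevention,take back
prevention,prescription drug monitoring
rescue,naloxone
rescue,narcan
rescue,overdose reversal
rescue,syringe exchange
intervention,treatment
intervention,medication
intervention,methadone
intervention,buprenorphine
intervention,naltrexone
intervention,suboxone
intervention,recovery
intervention,counseling
intervention,therapy
implementation,acceptability
implementation,adoption
implementation,feasibility
implementation,fidelity
implementation,implementation
sustainability,sustaining
sustainability,sustainment
sustainability,sustainability
sustainability,beyond funding
evaluation,monitor
evaluation,monitoring
evaluation,assessment
evaluation,feedback
evaluation,evaluation
evaluation,outcome
assistance,technical assistance
assistance,consultation
assistance,coaching
assistance,mentoring
assistance,facilitation
adaptation,adaptation
adaptation,tailoring
adaptation,modification
partnership,partnership
partnership,collaboration
partnership,coalition
partnership,stakeholder
partnership,interagency
education_strategies,learning collaborative
education_strategies,echo
education_strategies,train the trainer
education_strategies,continuing education
education_strategies,toolkit
consumer_engagement,peer support
consumer_engagement,peer recovery
consumer_engagement,consumer
consumer_engagement,family engagement
consumer_engagement,community engagement
financial_strategies,medicaid
financial_strategies,billing
financial_strategies,reimbursement
financial_strategies,insurance
financial_strategies,braided funding
financial_strategies,cpt
infrastructure,infrastructure
infrastructure,data system
infrastructure,workforce
infrastructure,hub and spoke
infrastructure,telehealth
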