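field,synonym,canonical
gender,man,man
gender,male,man
gender,men,man
gender,чоловік,man
gender,woman,woman
gender,female,woman
gender,women,woman
gender,жінка,woman
gender,other,other
gender,інше,other
marital_status,single,single
marital_status,неодружений,single
marital_status,неодружена,single
marital_status,married,married
marital_status,одружений,married
marital_status,одружена,married
marital_status,in a relationship,in-a-relationship
marital_status,in-a-relationship,in-a-relationship
marital_status,relationship,in-a-relationship
education,secondary,secondary
education,secondary school,secondary
education,середня,secondary
education,college,college
education,коледж,college
education,bachelor,bachelor
education,bachelor's,bachelor
education,бакалавр,bachelor
education,master or phd,master-or-phd
education,master-or-phd,master-or-phd
education,master,master-or-phd
education,phd,master-or-phd
education,магістр,master-or-phd
occupation_status,never occupied,never-occupied
occupation_status,never-occupied,never-occupied
occupation_status,not occupied,never-occupied
occupation_status,occupied,occupied
occupation_status,occupied at the time of writing,occupied
occupation_status,de-occupied,de-occupied
occupation_status,de occupied,de-occupied
occupation_status,deoccupied,de-occupied
occupation_status,liberated,de-occupied
trauma_history,holocaust,holocaust
trauma_history,голокост,holocaust
trauma_history,holodomor,holodomor
trauma_history,голодомор,holodomor
trauma_history,none,none
trauma_history,no,none
trauma_history,немає,none
trauma_history,other,other
trauma_history,інше,other
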