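sex,age_band,transition,point,lower,upper
men,55-59,N_to_NA,2.4,2.2,2.6
men,55-59,NA_to_AA,4.2,3.8,4.6
men,55-59,AA_to_P,2.6,2.4,2.9
men,55-59,P_to_C,18.1,16.7,19.5
men,60-64,N_to_NA,2.3,2.1,2.6
men,60-64,NA_to_AA,4.0,3.6,4.4
men,60-64,AA_to_P,3.1,2.8,3.3
men,60-64,P_to_C,19.2,18.1,20.3
men,65-69,N_to_NA,2.4,2.1,2.6
men,65-69,NA_to_AA,4.0,3.6,4.3
men,65-69,AA_to_P,3.8,3.5,4.1
men,65-69,P_to_C,21.3,20.3,22.4
men,70-74,N_to_NA,2.2,1.8,2.5
men,70-74,NA_to_AA,4.1,3.6,4.6
men,70-74,AA_to_P,5.1,4.8,5.5
men,70-74,P_to_C,20.6,19.5,21.7
men,75-79,N_to_NA,1.8,1.2,2.3
men,75-79,NA_to_AA,3.7,2.9,4.6
men,75-79,AA_to_P,5.2,4.6,5.8
men,75-79,P_to_C,20.1,18.9,21.4
women,55-59,N_to_NA,1.4,1.3,1.5
women,55-59,NA_to_AA,4.0,3.6,4.5
women,55-59,AA_to_P,2.5,2.2,2.7
women,55-59,P_to_C,21.3,19.5,23.4
women,60-64,N_to_NA,1.5,1.4,1.7
women,60-64,NA_to_AA,3.6,3.2,4.1
women,60-64,AA_to_P,2.7,2.4,3.0
women,60-64,P_to_C,22.5,20.9,24.2
women,65-69,N_to_NA,1.6,1.4,1.8
women,65-69,NA_to_AA,3.7,3.2,4.1
women,65-69,AA_to_P,3.8,3.5,4.1
women,65-69,P_to_C,21.9,20.6,23.3
women,70-74,N_to_NA,1.6,1.3,1.8
women,70-74,NA_to_AA,4.7,4.1,5.3
women,70-74,AA_to_P,5.0,4.5,5.4
women,70-74,P_to_C,20.8,19.4,22.2
women,75-79,N_to_NA,1.2,0.8,1.6
women,75-79,NA_to_AA,3.7,2.8,4.7
women,75-79,AA_to_P,5.6,4.9,6.3
women,75-79,P_to_C,19.2,17.9,20.7
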