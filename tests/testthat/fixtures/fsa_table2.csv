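state,input,next
Start,left,VX_plus
Start,right,VX_minus
Start,ton,VY_minus
Start,foot,VY_plus
Start,P_eq,Start
Start,P_plus,Start
Start,P_minus_moving,Start
Start,Touch,V_zero
Start,Fallen,Start
Start,Cross,Reset
Start,Null,Start
N_B,left,N_B
N_B,right,N_B
N_B,ton,N_B
N_B,foot,N_B
N_B,P_eq,N_B
N_B,P_plus,N_B
N_B,P_minus_moving,N_B
N_B,Touch,V_zero
N_B,Fallen,N_B
N_B,Cross,Reset
N_B,Null,V_zero
VX_plus,left,VX_plus
VX_plus,right,VX_minus
VX_plus,ton,VY_minus
VX_plus,foot,VY_plus
VX_plus,P_eq,VX_plus
VX_plus,P_plus,VX_plus
VX_plus,P_minus_moving,VX_plus
VX_plus,Touch,V_zero
VX_plus,Fallen,N_B
VX_plus,Cross,Reset
VX_plus,Null,VX_plus
VX_minus,left,VX_plus
VX_minus,right,VX_minus
VX_minus,ton,VY_minus
VX_minus,foot,VY_plus
VX_minus,P_eq,VX_minus
VX_minus,P_plus,VX_minus
VX_minus,P_minus_moving,VX_minus
VX_minus,Touch,V_zero
VX_minus,Fallen,N_B
VX_minus,Cross,Reset
VX_minus,Null,VX_minus
VY_plus,left,VX_plus
VY_plus,right,VX_minus
VY_plus,ton,VY_minus
VY_plus,foot,VY_plus
VY_plus,P_eq,VY_plus
VY_plus,P_plus,VY_plus
VY_plus,P_minus_moving,VY_plus
VY_plus,Touch,V_zero
VY_plus,Fallen,N_B
VY_plus,Cross,Reset
VY_plus,Null,VY_plus
VY_minus,left,VX_plus
VY_minus,right,VX_minus
VY_minus,ton,VY_minus
VY_minus,foot,VY_plus
VY_minus,P_eq,VY_minus
VY_minus,P_plus,VY_minus
VY_minus,P_minus_moving,VY_minus
VY_minus,Touch,V_zero
VY_minus,Fallen,N_B
VY_minus,Cross,Reset
VY_minus,Null,VY_minus
V_zero,left,VX_plus
V_zero,right,VX_minus
V_zero,ton,VY_minus
V_zero,foot,VY_plus
V_zero,P_eq,V_zero
V_zero,P_plus,V_zero
V_zero,P_minus_moving,V_zero
V_zero,Touch,V_zero
V_zero,Fallen,V_zero
V_zero,Cross,Reset
V_zero,Null,V_zero
Reset,left,Reset
Reset,right,Reset
Reset,ton,Reset
Reset,foot,Reset
Reset,P_eq,Reset
Reset,P_plus,Reset
Reset,P_minus_moving,Reset
Reset,Touch,Reset
Reset,Fallen,Reset
Reset,Cross,Reset
Reset,Null,Reset
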